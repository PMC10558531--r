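#' Build a reference-backbone sequence graph from haplotype variant tables
#'
#' The reference is split into segments at the union of all variant
#' breakpoints; each distinct alternate allele at a site becomes one
#' shared non-reference segment (deduplicated across samples by site and
#' allele string). Each sample's walk spells its haplotype: the
#' reference with its carried alleles substituted. Deletions add no
#' segment — the walk simply skips the deleted reference segments.
#' Adding a sample with no variants adds no segments or links.
#'
#' Variants must keep at least one reference base on each flank of every
#' chromosome so that each variant is anchored by reference segments on
#' both sides.
#'
#' @param reference Named character vector of chromosome sequences
#'   (A/C/G/T).
#' @param variants `data.frame` with columns `chrom`, `start` (1-based
#'   position of the first affected reference base; for insertions, of
#'   the base before which the insertion sits — the insertion then lies
#'   between `start - 1` and `start`), `ref_allele` (possibly empty),
#'   `alt_allele` (possibly empty) and `sample`. Intervals must be
#'   non-overlapping within a sample.
#' @param samples Optional character vector of sample names (so samples
#'   with no variants still get walks); defaults to the samples present
#'   in `variants`.
#' @param reference_name Walk name for the reference backbone.
#' @return A `sequence_graph` with elements `segments` (named character
#'   vector), `links` (`data.frame`: from, from_orient, to, to_orient),
#'   `walks` (per sample, a named list of per-chromosome segment-id
#'   vectors), `reference_walk` (name) and `segment_origin`
#'   (`"reference"` or `"non-reference"` per segment).
#' @examples
#' ref <- c(chr1 = "ACGTACGTACGTACGTACGT")
#' v <- data.frame(chrom = "chr1", start = 5, ref_allele = "ACGT",
#'                 alt_allele = "", sample = "S1")
#' g <- build_graph(ref, v)
#' graph_stats(g)$n_segments
#' @export
build_graph <- function(reference, variants, samples = NULL,
                        reference_name = "REF") {
  stopifnot(is.character(reference), length(reference) >= 1,
            !is.null(names(reference)))
  need <- c("chrom", "start", "ref_allele", "alt_allele", "sample")
  if (!all(need %in% names(variants)))
    stop_pansv("variant table needs columns: %s", paste(need, collapse = ", "))
  variants <- as.data.frame(variants)
  variants$ref_allele <- toupper(as.character(variants$ref_allele))
  variants$ref_allele[is.na(variants$ref_allele)] <- ""
  variants$alt_allele <- toupper(as.character(variants$alt_allele))
  variants$alt_allele[is.na(variants$alt_allele)] <- ""
  samples <- samples %||% sort(unique(variants$sample))
  if (reference_name %in% samples)
    stop_pansv("reference walk name '%s' collides with a sample", reference_name)

  # validate coordinates, reference alleles and per-sample non-overlap
  L <- nchar(reference)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (!v$chrom %in% names(reference))
      stop_pansv("sample %s: unknown chromosome '%s'", v$sample, v$chrom)
    rl <- nchar(v$ref_allele)
    s0 <- v$start - 1L               # 0-based interior start
    if (s0 < 1L || s0 + rl > L[[v$chrom]] - 1L)
      stop_pansv("sample %s: variant at %s:%d leaves no reference flank",
                 v$sample, v$chrom, v$start)
    if (rl > 0) {
      found <- substr(reference[[v$chrom]], v$start, v$start + rl - 1L)
      if (found != v$ref_allele)
        stop_pansv("sample %s: ref allele mismatch at %s:%d (stated %s, reference has %s)",
                   v$sample, v$chrom, v$start,
                   abbreviate_allele(v$ref_allele), abbreviate_allele(found))
    }
    if (v$alt_allele == v$ref_allele)
      stop_pansv("sample %s: alt equals ref at %s:%d (not a variant)",
                 v$sample, v$chrom, v$start)
  }
  for (s in unique(variants$sample)) {
    for (ch in unique(variants$chrom[variants$sample == s])) {
      d <- variants[variants$sample == s & variants$chrom == ch, ]
      d <- d[order(d$start), ]
      s0 <- d$start - 1L
      e0 <- s0 + nchar(d$ref_allele)
      if (nrow(d) > 1 && any(s0[-1] < e0[-nrow(d)]))
        stop_pansv("sample %s: overlapping variant intervals on %s", s, ch)
    }
  }

  segments <- character(0)
  origin <- character(0)
  ref_walk <- list()
  walks <- stats::setNames(
    rep(list(stats::setNames(vector("list", length(reference)),
                             names(reference))), length(samples)),
    samples)

  alt_seg_of <- new.env(parent = emptyenv())  # (chrom:s0:e0:alt) -> segment id
  n_alt <- 0L
  seg_counter <- 0L

  for (ch in names(reference)) {
    vch <- variants[variants$chrom == ch, , drop = FALSE]
    s0 <- vch$start - 1L
    e0 <- s0 + nchar(vch$ref_allele)
    bp <- sort(unique(c(0L, L[[ch]], s0, e0)))
    # reference segments between consecutive breakpoints
    seg_ids <- character(length(bp) - 1L)
    for (i in seq_len(length(bp) - 1L)) {
      seg_counter <- seg_counter + 1L
      id <- paste0("s", seg_counter)
      seg_ids[i] <- id
      segments[[id]] <- substr(reference[[ch]], bp[i] + 1L, bp[i + 1L])
      origin[[id]] <- "reference"
    }
    ref_walk[[ch]] <- seg_ids
    seg_start <- bp[-length(bp)]  # 0-based start per reference segment

    for (s in samples) {
      d <- vch[vch$sample == s, , drop = FALSE]
      if (nrow(d) == 0) { walks[[s]][[ch]] <- seg_ids; next }
      d <- d[order(d$start), ]
      walk <- character(0)
      cursor <- 0L  # 0-based reference position spelled so far
      for (i in seq_len(nrow(d))) {
        v_s0 <- d$start[i] - 1L
        v_e0 <- v_s0 + nchar(d$ref_allele[i])
        # reference segments up to the variant
        take <- seg_start >= cursor & seg_start < v_s0
        walk <- c(walk, seg_ids[take])
        if (d$alt_allele[i] != "") {
          key <- paste(ch, v_s0, v_e0, d$alt_allele[i], sep = ":")
          id <- if (exists(key, envir = alt_seg_of)) get(key, envir = alt_seg_of)
          else {
            n_alt <- n_alt + 1L
            aid <- paste0("a", n_alt)
            segments[[aid]] <- d$alt_allele[i]
            origin[[aid]] <- "non-reference"
            assign(key, aid, envir = alt_seg_of)
            aid
          }
          walk <- c(walk, id)
        }
        cursor <- v_e0
      }
      take <- seg_start >= cursor
      walk <- c(walk, seg_ids[take])
      walks[[s]][[ch]] <- walk
    }
  }

  all_walks <- c(stats::setNames(list(ref_walk), reference_name), walks)
  links <- derive_links(all_walks)
  structure(list(segments = segments, links = links, walks = all_walks,
                 reference_walk = reference_name, segment_origin = origin),
            class = "sequence_graph")
}

derive_links <- function(walks) {
  pairs <- unique(do.call(rbind, lapply(walks, function(w)
    do.call(rbind, lapply(w, function(v) {
      if (length(v) < 2) return(NULL)
      cbind(v[-length(v)], v[-1])
    })))))
  if (is.null(pairs))
    pairs <- matrix(character(0), 0, 2)
  data.frame(from = pairs[, 1], from_orient = rep("+", nrow(pairs)),
             to = pairs[, 2], to_orient = rep("+", nrow(pairs)),
             stringsAsFactors = FALSE)
}

abbreviate_allele <- function(a, max = 12) {
  if (nchar(a) <= max) a else paste0(substr(a, 1, max), "...<", nchar(a), "bp>")
}

#' @export
print.sequence_graph <- function(x, ...) {
  st <- graph_stats(x)
  cat(sprintf(
    "sequence_graph: %d segments, %d links, %d walks (reference: %s)\n  total %d bp, non-reference %d bp\n",
    st$n_segments, st$n_links, length(x$walks), x$reference_walk,
    st$total_length, st$nonref_length))
  invisible(x)
}

#' Validate walk/link consistency and the reference spelling invariant
#' @param graph A `sequence_graph`.
#' @return `TRUE` invisibly; errors on inconsistency.
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "sequence_graph"))
  if (!graph$reference_walk %in% names(graph$walks))
    stop_pansv("reference walk '%s' missing", graph$reference_walk)
  if (any(nchar(graph$segments) == 0)) stop_pansv("empty segment present")
  lk <- paste(graph$links$from, graph$links$to)
  for (s in names(graph$walks)) for (ch in names(graph$walks[[s]])) {
    w <- graph$walks[[s]][[ch]]
    if (!all(w %in% names(graph$segments)))
      stop_pansv("walk %s/%s uses unknown segments", s, ch)
    if (length(w) > 1) {
      pw <- paste(w[-length(w)], w[-1])
      if (!all(pw %in% lk))
        stop_pansv("walk %s/%s traverses a missing link", s, ch)
    }
  }
  invisible(TRUE)
}

#' Spell a walk's sequence
#' @param graph A `sequence_graph`.
#' @param sample Walk name.
#' @param chrom Chromosome; default all, returned as a named vector.
#' @return Named character vector of spelled sequences.
#' @export
spell_walk <- function(graph, sample, chrom = NULL) {
  stopifnot(sample %in% names(graph$walks))
  w <- graph$walks[[sample]]
  chrom <- chrom %||% names(w)
  vapply(chrom, function(ch)
    paste(graph$segments[w[[ch]]], collapse = ""), character(1))
}

#' Summary statistics of a sequence graph
#'
#' Reports segment and link counts, total and non-reference sequence
#' length, and per-sample novelty: the non-reference sequence its walks
#' traverse and the links used by that sample only (not by the
#' reference walk or any other sample).
#'
#' @param graph A `sequence_graph`.
#' @return List with `n_segments`, `n_links`, `total_length`,
#'   `nonref_length`, and `per_sample` (`data.frame`: sample,
#'   nonref_length, specific_links).
#' @export
graph_stats <- function(graph) {
  segs <- graph$segments
  nonref <- names(segs)[graph$segment_origin[names(segs)] == "non-reference"]
  samples <- setdiff(names(graph$walks), graph$reference_walk)
  walk_links <- lapply(graph$walks, function(w)
    unique(unlist(lapply(w, function(v)
      if (length(v) > 1) paste(v[-length(v)], v[-1]) else character(0)))))
  per <- do.call(rbind, lapply(samples, function(s) {
    used <- unique(unlist(graph$walks[[s]]))
    other <- unique(unlist(walk_links[setdiff(names(graph$walks), s)]))
    data.frame(sample = s,
               nonref_length = sum(nchar(segs[intersect(used, nonref)])),
               specific_links = sum(!walk_links[[s]] %in% other))
  }))
  list(n_segments = length(segs), n_links = nrow(graph$links),
       total_length = sum(nchar(segs)),
       nonref_length = sum(nchar(segs[nonref])),
       per_sample = per %||% data.frame(sample = character(0),
                                        nonref_length = integer(0),
                                        specific_links = integer(0)))
}

#' Cumulative graph growth as samples are added
#'
#' Rebuilds the graph with the first `k` samples of `order` for each
#' `k` and reports the cumulative total graph length, mirroring
#' pan-genome size saturation as assemblies are added.
#'
#' @inheritParams build_graph
#' @param order Character vector: the order in which samples are added.
#' @return `data.frame` with `k`, `sample`, `total_length`,
#'   `nonref_length`.
#' @export
pan_graph_growth <- function(reference, variants, order,
                             reference_name = "REF") {
  recs <- lapply(seq_along(order), function(k) {
    g <- build_graph(reference,
                     variants[variants$sample %in% order[seq_len(k)], ,
                              drop = FALSE],
                     samples = order[seq_len(k)],
                     reference_name = reference_name)
    st <- graph_stats(g)
    data.frame(k = k, sample = order[k], total_length = st$total_length,
               nonref_length = st$nonref_length)
  })
  do.call(rbind, recs)
}
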