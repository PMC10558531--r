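#' Detect reference-anchored bubbles in a sequence graph
#'
#' A bubble is a stretch between two reference-backbone anchor segments
#' where sample walks diverge into two or more distinct spelled
#' sequences. Each walk's deviations from the reference walk are located
#' by aligning its reference segments to the backbone; deviations whose
#' reference intervals overlap or touch are merged, so nested or
#' coinciding alternations form a single (typically multiallelic)
#' bubble. Anchors are the nearest reference segments flanking the
#' merged interval; every walk traverses both anchors and spells exactly
#' one allele between them.
#'
#' @param graph A `sequence_graph` (see [build_graph()]).
#' @return An object of class `bubble_set`: a `data.frame` with one row
#'   per bubble, in coordinate order, with columns `chrom`, `pos`
#'   (1-based position of the reference base immediately before the
#'   bubble interior), `end0` / `start0` (0-based half-open interior),
#'   `source`, `sink` (anchor segment ids), `ref_allele` (interior
#'   reference spelling, possibly empty) and list-columns `alleles`
#'   (distinct spelled interior sequences, reference first) and
#'   `allele_samples` (per-allele sample sets, reference walk excluded).
#' @export
detect_bubbles <- function(graph) {
  stopifnot(inherits(graph, "sequence_graph"))
  validate_graph(graph)
  ref <- graph$walks[[graph$reference_walk]]
  samples <- setdiff(names(graph$walks), graph$reference_walk)
  out <- list()

  for (ch in names(ref)) {
    ref_ids <- ref[[ch]]
    seg_len <- nchar(graph$segments[ref_ids])
    seg_end <- cumsum(seg_len)                 # 0-based exclusive end
    seg_start <- seg_end - seg_len             # 0-based start

    # collect deviations (s0, e0, sample) from every sample walk
    dev <- list()
    for (s in samples) {
      w <- graph$walks[[s]][[ch]]
      ridx <- match(w, ref_ids)
      hit <- which(!is.na(ridx))
      if (length(hit) == 0 ||
          is.na(ridx[1]) || ridx[hit[1]] != 1L ||
          is.na(ridx[length(w)]) || ridx[hit[length(hit)]] != length(ref_ids))
        stop_pansv("walk %s/%s does not start and end on the reference backbone", s, ch)
      if (any(diff(ridx[hit]) <= 0))
        stop_pansv("walk %s/%s visits reference segments out of order", s, ch)
      for (i in seq_len(length(hit) - 1L)) {
        a <- hit[i]; b <- hit[i + 1L]
        skipped <- ridx[b] - ridx[a] > 1L
        inserted <- b - a > 1L
        if (skipped || inserted) {
          dev[[length(dev) + 1L]] <- c(seg_end[ridx[a]], seg_start[ridx[b]])
        }
      }
    }
    if (length(dev) == 0) next
    ivals <- do.call(rbind, dev)
    ivals <- ivals[order(ivals[, 1], ivals[, 2]), , drop = FALSE]
    # merge intervals that overlap or touch (closed-interval semantics)
    merged <- list(ivals[1, ])
    for (i in seq_len(nrow(ivals))[-1]) {
      cur <- merged[[length(merged)]]
      if (ivals[i, 1] <= cur[2])
        merged[[length(merged)]] <- c(cur[1], max(cur[2], ivals[i, 2]))
      else merged[[length(merged) + 1L]] <- ivals[i, ]
    }

    for (m in merged) {
      S0 <- m[1]; E0 <- m[2]
      src <- ref_ids[match(S0, seg_end)]
      snk <- ref_ids[match(E0, seg_start)]
      if (is.na(src) || is.na(snk))
        stop_pansv("bubble on %s lacks a reference anchor (interval %d-%d)",
                   ch, S0, E0)
      ref_allele <- spell_between(graph, graph$reference_walk, ch, src, snk)
      spelled <- vapply(samples, function(s)
        spell_between(graph, s, ch, src, snk), character(1))
      alleles <- unique(c(ref_allele, unname(spelled)))
      allele_samples <- lapply(alleles, function(a)
        sort(samples[!is.na(spelled) & spelled == a]))
      src_seq <- graph$segments[[src]]
      out[[length(out) + 1L]] <- list(
        chrom = ch, pos = as.integer(S0), start0 = as.integer(S0),
        end0 = as.integer(E0), source = src, sink = snk,
        anchor_base = substr(src_seq, nchar(src_seq), nchar(src_seq)),
        ref_allele = ref_allele, alleles = alleles,
        allele_samples = allele_samples)
    }
  }
  bubble_set(out)
}

# Spell the concatenated segments strictly between src and snk on a walk;
# NA if the walk does not traverse both anchors.
spell_between <- function(graph, sample, chrom, src, snk) {
  w <- graph$walks[[sample]][[chrom]]
  i <- match(src, w); j <- match(snk, w)
  if (is.na(i) || is.na(j) || j < i) return(NA_character_)
  if (j == i + 1L) return("")
  paste(graph$segments[w[(i + 1L):(j - 1L)]], collapse = "")
}

bubble_set <- function(records) {
  if (length(records) == 0) {
    d <- data.frame(chrom = character(0), pos = integer(0),
                    start0 = integer(0), end0 = integer(0),
                    source = character(0), sink = character(0),
                    anchor_base = character(0), ref_allele = character(0))
    d$alleles <- I(list()); d$allele_samples <- I(list())
  } else {
    d <- data.frame(
      chrom = vapply(records, `[[`, "", "chrom"),
      pos = vapply(records, `[[`, 0L, "pos"),
      start0 = vapply(records, `[[`, 0L, "start0"),
      end0 = vapply(records, `[[`, 0L, "end0"),
      source = vapply(records, `[[`, "", "source"),
      sink = vapply(records, `[[`, "", "sink"),
      anchor_base = vapply(records, `[[`, "", "anchor_base"),
      ref_allele = vapply(records, `[[`, "", "ref_allele"),
      stringsAsFactors = FALSE)
    d$alleles <- I(lapply(records, `[[`, "alleles"))
    d$allele_samples <- I(lapply(records, `[[`, "allele_samples"))
    d <- d[order(d$chrom, d$pos), , drop = FALSE]
    rownames(d) <- NULL
  }
  class(d) <- c("bubble_set", class(d))
  d
}
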