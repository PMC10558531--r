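#' Call classified structural variants from bubbles
#'
#' Each bubble yields one SV. Sites with exactly one non-reference
#' allele are biallelic and subtyped by allele content: empty reference
#' allele = insertion, empty alternate allele = deletion, both non-empty
#' = divergent (which covers inversions and other balanced
#' replacements). Sites with two or more non-reference alleles are
#' multiallelic. SV length is the maximum allele length (reference
#' included), used both for the minimum-length filter and for `SVLEN`.
#'
#' @param bubbles A `bubble_set` from [detect_bubbles()].
#' @param min_len Minimum SV length in bp (default 50); shorter variants
#'   are dropped.
#' @return An object of class `sv_set`: a `data.frame` with columns
#'   `chrom`, `pos` (anchor-base position, 1-based), `end`
#'   (`pos + nchar(ref_allele)`), `ref_allele`, `sv_type`
#'   (`biallelic_insertion`, `biallelic_deletion`, `biallelic_divergent`
#'   or `multiallelic`), `sv_length`, `source`, `sink` and list-columns
#'   `alt_alleles` (sorted by length then lexicographically) and
#'   `carriers` (per-alt sample sets) plus `ref_carriers`.
#' @export
call_svs <- function(bubbles, min_len = 50) {
  stopifnot(inherits(bubbles, "bubble_set"), min_len >= 0)
  recs <- list()
  for (i in seq_len(nrow(bubbles))) {
    b <- bubbles[i, ]
    alleles <- b$alleles[[1]]
    samples <- b$allele_samples[[1]]
    is_ref <- alleles == b$ref_allele
    if (all(is_ref))
      stop_pansv("bubble at %s:%d has only the reference allele (not a variant site)",
                 b$chrom, b$pos)
    alts <- alleles[!is_ref]
    alt_samples <- samples[!is_ref]
    ord <- order(nchar(alts), alts)
    alts <- alts[ord]; alt_samples <- alt_samples[ord]
    n_alt <- length(alts)
    sv_type <- if (n_alt >= 2) "multiallelic"
    else if (b$ref_allele == "") "biallelic_insertion"
    else if (alts[1] == "") "biallelic_deletion"
    else "biallelic_divergent"
    sv_length <- max(nchar(c(b$ref_allele, alts)))
    if (sv_length < min_len) next
    recs[[length(recs) + 1L]] <- list(
      chrom = b$chrom, pos = b$pos, end = b$pos + nchar(b$ref_allele),
      anchor_base = b$anchor_base,
      ref_allele = b$ref_allele, sv_type = sv_type,
      sv_length = as.integer(sv_length),
      source = b$source, sink = b$sink,
      alt_alleles = alts, carriers = alt_samples,
      ref_carriers = if (any(is_ref)) samples[is_ref][[1]] else character(0))
  }
  sv_set(recs)
}

sv_set <- function(records) {
  if (length(records) == 0) {
    d <- data.frame(chrom = character(0), pos = integer(0), end = integer(0),
                    anchor_base = character(0),
                    ref_allele = character(0), sv_type = character(0),
                    sv_length = integer(0), source = character(0),
                    sink = character(0))
    d$alt_alleles <- I(list()); d$carriers <- I(list())
    d$ref_carriers <- I(list())
  } else {
    d <- data.frame(
      chrom = vapply(records, `[[`, "", "chrom"),
      pos = vapply(records, function(r) as.integer(r$pos), 0L),
      end = vapply(records, function(r) as.integer(r$end), 0L),
      anchor_base = vapply(records, function(r)
        as.character(r$anchor_base %||% "N"), ""),
      ref_allele = vapply(records, `[[`, "", "ref_allele"),
      sv_type = vapply(records, `[[`, "", "sv_type"),
      sv_length = vapply(records, `[[`, 0L, "sv_length"),
      source = vapply(records, `[[`, "", "source"),
      sink = vapply(records, `[[`, "", "sink"),
      stringsAsFactors = FALSE)
    d$alt_alleles <- I(lapply(records, `[[`, "alt_alleles"))
    d$carriers <- I(lapply(records, `[[`, "carriers"))
    d$ref_carriers <- I(lapply(records, `[[`, "ref_carriers"))
    d <- d[order(d$chrom, d$pos), , drop = FALSE]
    rownames(d) <- NULL
  }
  class(d) <- c("sv_set", class(d))
  d
}

#' @export
print.sv_set <- function(x, ...) {
  cat(sprintf("sv_set: %d structural variants\n", nrow(x)))
  if (nrow(x)) print(table(x$sv_type))
  invisible(x)
}

#' Genotype sample walks at called SV sites
#'
#' Assigns each sample the allele its walk spells between an SV's
#' anchors. Biallelic sites are coded 0 (reference) / 2 (alternate,
#' homozygous convention); multiallelic sites are coded 0 for the
#' reference allele and the allele index (1, 2, ...) for alternates.
#' Walks that do not traverse both anchors get a missing call.
#'
#' @param svs An `sv_set` from [call_svs()].
#' @param graph The `sequence_graph` the SVs were called from.
#' @return Numeric matrix, samples x SVs, column names `chrom:pos`.
#' @export
genotype_walks <- function(svs, graph) {
  stopifnot(inherits(svs, "sv_set"), inherits(graph, "sequence_graph"))
  samples <- setdiff(names(graph$walks), graph$reference_walk)
  g <- matrix(NA_real_, length(samples), nrow(svs),
              dimnames = list(samples,
                              if (nrow(svs)) paste0(svs$chrom, ":", svs$pos)
                              else character(0)))
  for (j in seq_len(nrow(svs))) {
    alts <- svs$alt_alleles[[j]]
    multi <- length(alts) >= 2
    for (s in samples) {
      spelled <- spell_between(graph, s, svs$chrom[j],
                               svs$source[j], svs$sink[j])
      if (is.na(spelled)) next
      if (spelled == svs$ref_allele[j]) { g[s, j] <- 0; next }
      k <- match(spelled, alts)
      if (!is.na(k)) g[s, j] <- if (multi) k else 2
    }
  }
  g
}

#' Convert walk genotypes and an SV set into a genotype panel
#'
#' Convenience wrapper around [genotype_walks()] that returns a
#' [genotype_panel()] with variant class `"SV"`.
#'
#' @inheritParams genotype_walks
#' @return A [genotype_panel()].
#' @export
sv_panel <- function(svs, graph) {
  g <- genotype_walks(svs, graph)
  variants <- data.frame(id = colnames(g), chrom = svs$chrom, pos = svs$pos,
                         class = "SV", stringsAsFactors = FALSE)
  genotype_panel(g, variants, rownames(g))
}
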