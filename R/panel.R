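#' Genotype panel container
#'
#' A light container for a samples-by-variants dosage table in the
#' homozygous (inbred) coding: 0 = homozygous reference, 2 = homozygous
#' alternate, `NA` = missing. *A. thaliana* ecotypes are selfing and
#' effectively fully homozygous, so heterozygous dosages never occur.
#'
#' @param genotypes Numeric matrix, samples in rows, variants in columns,
#'   values in `{0, 2, NA}` (multiallelic sites may carry allele indices).
#' @param variants `data.frame` with one row per variant and columns
#'   `id`, `chrom`, `pos` (1-based bp) and `class` (`"SNP"` or `"SV"`).
#' @param sample_ids Character vector of row identifiers.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(genotypes, variants, sample_ids = rownames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(genotypes)))
  stopifnot(
    nrow(variants) == ncol(genotypes),
    length(sample_ids) == nrow(genotypes),
    all(c("id", "chrom", "pos", "class") %in% names(variants))
  )
  if (anyDuplicated(variants$id)) stop_pansv("duplicate variant ids in panel")
  rownames(genotypes) <- sample_ids
  colnames(genotypes) <- variants$id
  structure(
    list(genotypes = genotypes, variants = as.data.frame(variants),
         sample_ids = sample_ids),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "genotype_panel: %d samples x %d variants (%d SNP, %d SV), %.1f%% missing\n",
    nrow(x$genotypes), ncol(x$genotypes),
    sum(x$variants$class == "SNP"), sum(x$variants$class == "SV"),
    100 * mean(is.na(x$genotypes))
  ))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$genotypes)

#' Subset a panel by variant and/or sample index
#' @param panel A [genotype_panel()].
#' @param variants Index vector into variant columns (logical/integer/character).
#' @param samples Index vector into sample rows.
#' @return A `genotype_panel`.
#' @export
subset_panel <- function(panel, variants = NULL, samples = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$genotypes
  v <- panel$variants
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, v$id)
    g <- g[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
  }
  s <- panel$sample_ids
  if (!is.null(samples)) {
    g <- g[samples, , drop = FALSE]
    s <- rownames(g)
  }
  genotype_panel(g, v, s)
}

#' Per-variant minor allele frequency
#'
#' Frequencies are computed on the dosage scale (dosage / 2 over
#' non-missing samples) and folded to the minor allele, so values lie in
#' `[0, 0.5]`. Multiallelic codes (> 2) are treated as carrying a
#' non-reference allele.
#'
#' @param panel A [genotype_panel()].
#' @return Named numeric vector of MAFs (NA where all calls are missing).
#' @export
panel_maf <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$genotypes
  f <- colMeans(g > 0, na.rm = TRUE)  # alt-carrier frequency
  maf <- pmin(f, 1 - f)
  maf[!is.finite(maf)] <- NA_real_
  names(maf) <- panel$variants$id
  maf
}
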