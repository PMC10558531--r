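#' Variant- and sample-level panel quality control
#'
#' One deterministic pass, variants first then samples: drops variants
#' with missing fraction above `variant_missing_max` or minor allele
#' frequency below `maf_min`, then drops samples whose missing fraction
#' (over the retained variants) exceeds `sample_missing_max`. The SNP
#' defaults mirror the common plink setting `--geno 0.1 --maf 0.03
#' --mind 0.1`; for SV panels, `(0.5, 0.05, 1)` reproduces the usual SV
#' quality filter (missing rate 0.5, MAF 0.05).
#'
#' @param panel A [genotype_panel()].
#' @param variant_missing_max Maximum per-variant missing fraction
#'   (default 0.1).
#' @param maf_min Minimum minor allele frequency (default 0.03).
#' @param sample_missing_max Maximum per-sample missing fraction
#'   (default 0.1).
#' @return List with `panel` (filtered) and `report` (`data.frame` of
#'   counts dropped per rule, in application order).
#' @export
filter_panel <- function(panel, variant_missing_max = 0.1, maf_min = 0.03,
                         sample_missing_max = 0.1) {
  stopifnot(inherits(panel, "genotype_panel"),
            variant_missing_max >= 0, variant_missing_max <= 1,
            maf_min >= 0, maf_min <= 0.5,
            sample_missing_max >= 0, sample_missing_max <= 1)
  g <- panel$genotypes
  vmiss <- colMeans(is.na(g))
  maf <- panel_maf(panel)
  drop_miss <- vmiss > variant_missing_max
  drop_maf <- !drop_miss & (is.na(maf) | maf < maf_min)
  keep_v <- !(drop_miss | drop_maf)
  if (!any(keep_v)) stop_pansv("all variants removed by QC")
  g2 <- g[, keep_v, drop = FALSE]
  smiss <- rowMeans(is.na(g2))
  keep_s <- smiss <= sample_missing_max
  if (!any(keep_s)) stop_pansv("all samples removed by QC")
  report <- data.frame(
    rule = c("variant_missing", "variant_maf", "sample_missing"),
    threshold = c(variant_missing_max, maf_min, sample_missing_max),
    dropped = c(sum(drop_miss), sum(drop_maf), sum(!keep_s)))
  out <- genotype_panel(g2[keep_s, , drop = FALSE],
                        panel$variants[keep_v, , drop = FALSE],
                        panel$sample_ids[keep_s])
  if (!is.null(panel$subpop)) out$subpop <- panel$subpop[keep_s]
  list(panel = out, report = report)
}

#' Squared Pearson correlation between two dosage vectors
#'
#' LD r-squared over pairwise-complete samples. Undefined (returned as
#' `NA`) when fewer than two complete pairs remain or either vector has
#' zero variance after missing removal.
#'
#' @param g1,g2 Numeric dosage vectors of equal length.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @examples
#' ld_r2(c(0, 0, 2, 2), c(2, 2, 0, 0))  # 1
#' ld_r2(c(0, 0, 2, 2), c(0, 2, 0, 2))  # 0
#' @export
ld_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Tag SVs by nearby SNPs through linkage disequilibrium
#'
#' For every SV in the panel, computes the maximum r-squared against
#' SNPs within `window` bp on the same chromosome; the SV is "tagged"
#' when that maximum exceeds `ld_cutoff` — i.e. a SNP array would see
#' it. Also returns the tagging curve (tagged count per cutoff) over a
#' grid of cutoffs.
#'
#' @param panel A [genotype_panel()] containing both SNPs and SVs.
#' @param ld_cutoff Tagging threshold on r-squared (default 0.6).
#' @param window Search window in bp on each side (default 1e5).
#' @param cutoff_grid Cutoffs for the tagging curve.
#' @return List with `per_sv` (`data.frame`: id, chrom, pos, max_r2,
#'   tagged, best_snp), `n_tagged`, `fraction_tagged` and `curve`
#'   (`data.frame`: cutoff, n_tagged).
#' @export
tag_svs_by_snps <- function(panel, ld_cutoff = 0.6, window = 1e5,
                            cutoff_grid = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(inherits(panel, "genotype_panel"))
  v <- panel$variants
  is_sv <- v$class == "SV"
  is_snp <- v$class == "SNP"
  if (!any(is_sv) || !any(is_snp))
    stop_pansv("panel must contain both SNPs and SVs")
  svs <- which(is_sv)
  per <- data.frame(id = v$id[svs], chrom = v$chrom[svs], pos = v$pos[svs],
                    max_r2 = NA_real_, tagged = FALSE,
                    best_snp = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(svs)) {
    j <- svs[i]
    near <- which(is_snp & v$chrom == v$chrom[j] &
                    abs(v$pos - v$pos[j]) <= window)
    if (length(near) == 0) next
    r2 <- vapply(near, function(k)
      ld_r2(panel$genotypes[, j], panel$genotypes[, k]), numeric(1))
    if (all(is.na(r2))) next
    best <- which.max(r2)
    per$max_r2[i] <- r2[best]
    per$best_snp[i] <- v$id[near[best]]
  }
  per$tagged <- !is.na(per$max_r2) & per$max_r2 > ld_cutoff
  curve <- data.frame(
    cutoff = cutoff_grid,
    n_tagged = vapply(cutoff_grid, function(ct)
      sum(!is.na(per$max_r2) & per$max_r2 > ct), 0L))
  list(per_sv = per, n_tagged = sum(per$tagged),
       fraction_tagged = mean(per$tagged), curve = curve)
}
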