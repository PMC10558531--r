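#' Standardize a phenotype to mean 0, variance 1
#'
#' Missing values are ignored for the moments and propagated to the
#' output. Idempotent; association results are invariant to it.
#'
#' @param y Numeric vector with positive variance.
#' @return Standardized vector with names preserved.
#' @export
standardize_phenotype <- function(y) {
  s <- stats::sd(y, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop_pansv("phenotype is constant; cannot standardize")
  (y - mean(y, na.rm = TRUE)) / s
}

#' Mixed-model association scan over a genotype panel
#'
#' The standard one-kinship linear mixed model: the null variance
#' components of `y = mu + g + e`, `Var = sigma2_g G + sigma2_e I`, are
#' estimated once by REML ([fit_single_component()]), then every
#' variant passing the MAF filter is tested by generalized least
#' squares in the whitened space — `y` and each mean-imputed dosage
#' vector are rotated by the inverse square root of the null
#' covariance, and the variant effect is the resulting OLS slope with a
#' Wald test against the asymptotic normal reference.
#'
#' @param y Phenotype vector (samples in panel order).
#' @param panel A [genotype_panel()].
#' @param G Kinship matrix used to correct for relatedness/population
#'   structure (default: computed from the whole panel).
#' @param maf_min Minimum MAF; rarer variants are skipped (default 0.05).
#' @param classes Variant classes to test (default both).
#' @param null_fit Optional precomputed `variance_components` for the
#'   null model; with `sigma2 = c(g = 0)` the scan reduces to ordinary
#'   least squares per variant.
#' @return An `assoc_result` `data.frame`: id, chrom, pos, class, maf,
#'   beta, se, wald, p, neglog10p — one row per tested variant. The
#'   null fit is attached as attribute `"null_fit"`.
#' @export
lmm_assoc <- function(y, panel, G = NULL, maf_min = 0.05,
                      classes = c("SNP", "SV"), null_fit = NULL) {
  stopifnot(inherits(panel, "genotype_panel"),
            length(y) == nrow(panel$genotypes))
  G <- G %||% compute_kinship(panel)
  null_fit <- null_fit %||% fit_single_component(y, G)
  n <- length(y)
  # inverse square root of the null covariance (scale-free: relative
  # weights only affect betas through y's units, p-values unchanged)
  ed <- eigen(unclass(G), symmetric = TRUE)
  d <- null_fit$sigma2[["g"]] * pmax(ed$values, 0) + null_fit$sigma2_e
  Wh <- diag(1 / sqrt(d)) %*% t(ed$vectors)   # whitening rotation
  ys <- drop(Wh %*% y)
  ones <- drop(Wh %*% rep(1, n))

  maf <- panel_maf(panel)
  test_idx <- which(panel$variants$class %in% classes &
                      !is.na(maf) & maf >= maf_min)
  recs <- vector("list", length(test_idx))
  for (k in seq_along(test_idx)) {
    j <- test_idx[k]
    x <- panel$genotypes[, j]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    if (stats::sd(x) == 0) next
    xs <- drop(Wh %*% x)
    X <- cbind(ones, xs)
    XtX <- crossprod(X)
    Xty <- crossprod(X, ys)
    coef <- solve(XtX, Xty)
    r <- ys - X %*% coef
    df <- n - 2
    s2 <- sum(r^2) / df
    vb <- s2 * solve(XtX)[2, 2]
    beta <- coef[2, 1]
    se <- sqrt(vb)
    wald <- beta / se
    p <- 2 * stats::pnorm(-abs(wald))
    recs[[k]] <- data.frame(
      id = panel$variants$id[j], chrom = panel$variants$chrom[j],
      pos = panel$variants$pos[j], class = panel$variants$class[j],
      maf = maf[j], beta = beta, se = se, wald = wald, p = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(id = character(0), chrom = character(0),
                      pos = integer(0), class = character(0),
                      maf = numeric(0), beta = numeric(0), se = numeric(0),
                      wald = numeric(0), p = numeric(0))
  out$neglog10p <- -log10(out$p)
  rownames(out) <- NULL
  attr(out, "null_fit") <- null_fit
  class(out) <- c("assoc_result", class(out))
  out
}

#' Bonferroni genome-wide significance threshold
#'
#' `-log10(alpha / n_tests)`. `n_effective` substitutes an effective
#' number of independent tests when the panel is strongly correlated.
#'
#' @param n_tests Number of tests performed.
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_effective Optional effective test count overriding
#'   `n_tests`.
#' @return The threshold on the `-log10(p)` scale.
#' @examples
#' significance_threshold(1000)  # 4.301
#' @export
significance_threshold <- function(n_tests, alpha = 0.05,
                                   n_effective = NULL) {
  n <- n_effective %||% n_tests
  stopifnot(n >= 1)
  if (alpha <= 0 || alpha >= 1) stop_pansv("alpha must be in (0, 1)")
  -log10(alpha / n)
}
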