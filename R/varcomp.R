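#' Genomic relationship (kinship) matrix from a genotype panel
#'
#' Standardized GRM: `G = W %*% t(W) / m`, where `W` is the dosage
#' matrix with missing entries imputed to the column mean and each of
#' the `m` polymorphic variant columns centered and scaled to unit
#' variance. The diagonal then averages about 1 and `G` is positive
#' semi-definite by construction.
#'
#' @param panel A [genotype_panel()].
#' @param subset `"SNP"`, `"SV"` or `"all"`: which variant class to use.
#' @param exclude Optional character vector of variant ids to leave out
#'   (e.g. detected QTLs).
#' @return A `kinship_matrix`: the n x n matrix with sample dimnames and
#'   attribute `"m"` (number of variants used).
#' @export
compute_kinship <- function(panel, subset = c("all", "SNP", "SV"),
                            exclude = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  subset <- match.arg(subset)
  keep <- if (subset == "all") rep(TRUE, ncol(panel$genotypes))
  else panel$variants$class == subset
  if (!is.null(exclude)) keep <- keep & !panel$variants$id %in% exclude
  g <- panel$genotypes[, keep, drop = FALSE]
  if (nrow(g) < 2) stop_pansv("kinship needs >= 2 samples")
  W <- standardize_dosage(g)
  if (ncol(W) == 0) stop_pansv("no polymorphic variants for kinship")
  G <- tcrossprod(W) / ncol(W)
  dimnames(G) <- list(panel$sample_ids, panel$sample_ids)
  attr(G, "m") <- ncol(W)
  class(G) <- c("kinship_matrix", class(G))
  G
}

#' Design matrix Z with Z Z' = G
#'
#' Cholesky factorization of the kinship matrix, falling back to an
#' eigendecomposition with negative eigenvalues clipped at zero
#' (tolerance 1e-10) when G is rank deficient, so a factor is returned
#' for any symmetric positive semi-definite input.
#'
#' @param G A symmetric (kinship) matrix.
#' @param tol Symmetry/eigenvalue tolerance.
#' @return Matrix `Z` with `max(abs(Z %*% t(Z) - G))` below tolerance.
#' @export
kinship_design <- function(G, tol = 1e-8) {
  G <- unclass(G)
  if (max(abs(G - t(G))) > tol) stop_pansv("kinship matrix is not symmetric")
  G <- (G + t(G)) / 2
  Z <- tryCatch(t(chol(G)), error = function(e) NULL)
  if (is.null(Z)) {
    e <- eigen(G, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    lam[lam < 1e-10] <- 0
    Z <- e$vectors %*% diag(sqrt(lam), nrow = length(lam))
  }
  rownames(Z) <- rownames(G)
  Z
}

#' Variance components container
#' @keywords internal
variance_components <- function(mu, sigma2, sigma2_e, pve, loglik,
                                converged, model, message = "") {
  structure(list(mu = mu, sigma2 = sigma2, sigma2_e = sigma2_e, pve = pve,
                 loglik = loglik, converged = converged, model = model,
                 message = message),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("REML fit (%s): mu = %.4g, sigma2_e = %.4g%s\n", x$model,
              x$mu, x$sigma2_e,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  for (k in seq_along(x$sigma2))
    cat(sprintf("  sigma2_%s = %.4g  (PVE_%s = %.3f)\n",
                names(x$sigma2)[k], x$sigma2[[k]],
                names(x$pve)[k], x$pve[[k]]))
  invisible(x)
}

#' REML fit of the single-kinship mixed model
#'
#' Fits `y = mu + Z u + e` with `u ~ N(0, I sigma2_g)` and
#' `Z Z' = G`, i.e. the polygenic model with covariance
#' `sigma2_g G + sigma2_e I`, by restricted maximum likelihood. The
#' restricted log-likelihood is profiled over the heritability ratio on
#' an eigendecomposition of G, so the fit is a one-dimensional bounded
#' optimization and variance estimates are non-negative by construction.
#' The proportion of variance explained by the kinship is the
#' intraclass correlation `sigma2_g / (sigma2_g + sigma2_e)`.
#'
#' @param y Phenotype vector (length n, positive variance).
#' @param G n x n kinship matrix.
#' @return A `variance_components` with `sigma2 = c(g = ...)`,
#'   `sigma2_e`, `pve = c(g = ...)`, the restricted log-likelihood and a
#'   convergence flag.
#' @export
fit_single_component <- function(y, G) {
  G <- unclass(G)
  n <- length(y)
  stopifnot(nrow(G) == n, ncol(G) == n)
  if (anyNA(y)) {
    ok <- !is.na(y)
    y <- y[ok]; G <- G[ok, ok, drop = FALSE]; n <- length(y)
  }
  if (stats::sd(y) == 0) stop_pansv("phenotype has zero variance")
  ed <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam <- pmax(ed$values, 0)
  yt <- drop(crossprod(ed$vectors, y))
  xt <- drop(crossprod(ed$vectors, rep(1, n)))

  # restricted log-likelihood at variance ratio gamma = sigma2_g/sigma2_e,
  # profiled over mu and the total scale
  rll <- function(gamma) {
    d <- gamma * lam + 1
    xvx <- sum(xt^2 / d)
    beta <- sum(xt * yt / d) / xvx
    r <- yt - xt * beta
    rss <- sum(r^2 / d)
    s2e <- rss / (n - 1)
    -0.5 * ((n - 1) * log(s2e) + sum(log(d)) + log(xvx) + (n - 1))
  }
  # optimize over log-gamma, including the boundary gamma -> 0
  op <- stats::optimize(function(lg) -rll(exp(lg)), c(-12, 12), tol = 1e-9)
  cand <- c(exp(op$minimum), 0)
  ll <- vapply(cand, rll, numeric(1))
  gamma <- cand[which.max(ll)]
  d <- gamma * lam + 1
  xvx <- sum(xt^2 / d)
  mu <- sum(xt * yt / d) / xvx
  s2e <- sum((yt - xt * mu)^2 / d) / (n - 1)
  s2g <- gamma * s2e
  converged <- is.finite(max(ll)) && abs(op$minimum) < 12 - 1e-6 ||
    gamma == 0
  variance_components(
    mu = mu, sigma2 = c(g = s2g), sigma2_e = s2e,
    pve = c(g = s2g / (s2g + s2e)), loglik = max(ll),
    converged = converged, model = "single")
}

#' REML fit of the two-kinship composite mixed model
#'
#' Fits `y = mu + Z1 u1 + Z2 u2 + e` with independent random effects
#' whose covariances are `sigma2_u1 G_snp` and `sigma2_u2 G_sv`
#' (`Z_k Z_k' = G_k`), by direct maximization of the restricted
#' log-likelihood over the three variances with non-negativity bounds
#' (L-BFGS-B with analytic gradients). The variance proportions are
#' `PVE_snp = sigma2_u1 / (sigma2_u1 + sigma2_u2 + sigma2_e)` and
#' correspondingly for SVs.
#'
#' @param y Phenotype vector.
#' @param G_snp,G_sv Kinship matrices estimated from SNPs and from SVs.
#' @param max_iter Maximum optimizer iterations (default 200).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @return A `variance_components` with `sigma2 = c(u1 = ..., u2 = ...)`
#'   and `pve = c(snp = ..., sv = ...)`. Near-collinear kinships
#'   (`G_snp ~ G_sv`) trigger a convergence warning in `message`.
#' @export
fit_two_component <- function(y, G_snp, G_sv, max_iter = 200, tol = 1e-6) {
  G1 <- unclass(G_snp); G2 <- unclass(G_sv)
  n <- length(y)
  stopifnot(all(dim(G1) == n), all(dim(G2) == n))
  if (stats::sd(y) == 0) stop_pansv("phenotype has zero variance")
  X <- matrix(1, n, 1)
  vy <- stats::var(y)

  neg_rll_grad <- function(theta) {
    V <- theta[1] * G1 + theta[2] * G2 + diag(theta[3], n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(value = 1e10, grad = c(0, 0, 0)))
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    P <- Vi - ViX %*% solve(XtViX, t(ViX))
    Py <- P %*% y
    ldV <- 2 * sum(log(diag(ch)))
    value <- 0.5 * (ldV + log(XtViX[1, 1]) + sum(y * Py))
    grad <- vapply(list(G1, G2, diag(n)), function(Gk)
      0.5 * (sum(P * Gk) - drop(crossprod(Py, Gk %*% Py))), numeric(1))
    list(value = value, grad = grad)
  }
  cache <- new.env()
  fn <- function(theta) {
    r <- neg_rll_grad(theta)
    assign(paste(theta, collapse = ","), r, envir = cache)
    r$value
  }
  gr <- function(theta) {
    key <- paste(theta, collapse = ",")
    r <- if (exists(key, envir = cache)) get(key, envir = cache)
    else neg_rll_grad(theta)
    r$grad
  }
  start <- c(vy / 3, vy / 3, vy / 3)
  # a component whose kinship is numerically zero contributes nothing to
  # the covariance; its variance is unidentifiable and is pinned at 0
  upper <- c(ifelse(max(abs(G1)) == 0, 0, Inf),
             ifelse(max(abs(G2)) == 0, 0, Inf), Inf)
  start <- pmin(start, upper)
  op <- stats::optim(start, fn, gr, method = "L-BFGS-B",
                     lower = c(0, 0, vy * 1e-8), upper = upper,
                     control = list(maxit = max_iter, factr = 1e7))
  theta <- op$par
  # profile the fixed effect at the optimum
  V <- theta[1] * G1 + theta[2] * G2 + diag(theta[3], n)
  Vi <- chol2inv(chol(V))
  ViX <- Vi %*% X
  mu <- drop(solve(crossprod(X, ViX), crossprod(ViX, y)))
  total <- sum(theta)
  msg <- ""
  cG <- stats::cor(G1[lower.tri(G1)], G2[lower.tri(G2)])
  if (is.finite(cG) && cG > 0.99) {
    msg <- sprintf("SNP and SV kinships nearly collinear (r = %.3f); components poorly separated", cG)
    warning(msg)
  }
  if (op$convergence != 0 && nzchar(op$message %||% ""))
    msg <- paste(msg, op$message)
  variance_components(
    mu = mu, sigma2 = c(u1 = theta[1], u2 = theta[2]), sigma2_e = theta[3],
    pve = c(snp = theta[1] / total, sv = theta[2] / total),
    loglik = -op$value, converged = op$convergence == 0,
    model = "two-component", message = msg)
}

#' Restricted log-likelihood of a variance-component model
#'
#' Direct evaluation (Cholesky-based) of the restricted log-likelihood
#' of `y = mu + sum_k u_k + e`, `Var(y) = sum_k sigma2_k G_k +
#' sigma2_e I`, up to the REML additive constant. Exposed so the fits
#' can be checked against grid searches.
#'
#' @param y Phenotype vector.
#' @param sigma2 Numeric vector of component variances (same order as
#'   `G_list`).
#' @param sigma2_e Residual variance, > 0.
#' @param G_list List of kinship matrices.
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(y, sigma2, sigma2_e, G_list) {
  n <- length(y)
  stopifnot(length(sigma2) == length(G_list), sigma2_e > 0)
  V <- diag(sigma2_e, n)
  for (k in seq_along(G_list)) V <- V + sigma2[k] * unclass(G_list[[k]])
  ch <- chol(V)
  Vi <- chol2inv(ch)
  X <- matrix(1, n, 1)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  mu <- drop(solve(XtViX, crossprod(ViX, y)))
  r <- y - X %*% mu
  -0.5 * (2 * sum(log(diag(ch))) + log(XtViX[1, 1]) +
            drop(crossprod(r, Vi %*% r)))
}
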