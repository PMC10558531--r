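test_that("kinship matches the hand-computed standardized GRM on a toy", {
  g <- matrix(c(0, 2, 2,
                0, 0, 2), 3, 2)      # 3 samples x 2 variants
  p <- genotype_panel(g, data.frame(id = c("v1", "v2"), chrom = "1",
                                    pos = c(1, 2), class = "SNP"))
  W <- apply(g, 2, function(x) (x - mean(x)) / sd(x))
  expected <- W %*% t(W) / 2
  G <- compute_kinship(p)
  expect_equal(unclass(G), expected, ignore_attr = TRUE)
  expect_equal(attr(G, "m"), 2)
})

test_that("identical samples have off-diagonal kinship equal to diagonal", {
  g <- rbind(a = c(0, 2, 0, 2, 2), b = c(0, 2, 0, 2, 2),
             c = c(2, 0, 2, 0, 0))
  p <- genotype_panel(g, data.frame(id = paste0("v", 1:5), chrom = "1",
                                    pos = 1:5, class = "SNP"))
  G <- compute_kinship(p)
  expect_equal(G["a", "b"], G["a", "a"])
  expect_equal(G["a", "b"], G["b", "b"])
})

test_that("kinship of many unrelated samples has near-zero off-diagonals", {
  p <- simulate_genotype_matrix(100, 4000, 0, c(0.1, 0.5), 0, 1, seed = 70)
  G <- compute_kinship(p)
  expect_lt(max(abs(colMeans(unclass(G)) - diag(G) / 100)), 0.05)
  expect_equal(mean(diag(G)), 1, tolerance = 0.05)
  # missing dosages are mean-imputed, matrix stays PSD
  pm <- simulate_genotype_matrix(50, 500, 0, c(0.1, 0.5), 0.1, 1, seed = 71)
  Gm <- compute_kinship(pm)
  expect_gte(min(eigen(unclass(Gm), symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
})

test_that("kinship_design reconstructs G, including rank-deficient cases", {
  set.seed(72)
  Z0 <- matrix(rnorm(100), 20, 5)
  G <- Z0 %*% t(Z0)                       # rank 5 of 20: chol must fall back
  Z <- kinship_design(G)
  expect_lt(max(abs(Z %*% t(Z) - G)), 1e-8)
  expect_equal(kinship_design(diag(4)) %*% t(kinship_design(diag(4))),
               diag(4))
  # full-rank PSD
  Gf <- crossprod(matrix(rnorm(900), 30, 30)) / 30
  Zf <- kinship_design(Gf)
  expect_lt(max(abs(Zf %*% t(Zf) - Gf)), 1e-8)
  expect_error(kinship_design(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
})

test_that("single-component REML matches a restricted-likelihood grid search", {
  for (seed in c(81, 82)) {
    p <- simulate_genotype_matrix(50, 400, 0, c(0.1, 0.5), 0, 3, seed = seed)
    ph <- simulate_phenotype(p, 0.5, 0, seed = seed + 10)
    G <- compute_kinship(p)
    fit <- fit_single_component(ph$phenotype, G)
    grid <- grid_reml(ph$phenotype, G)
    expect_lt(abs(fit$pve[["g"]] - grid[["pve"]]), 0.011)
    # the fitted optimum is at least as good as any grid point
    expect_gte(rll_direct(ph$phenotype, G, fit$sigma2[["g"]], fit$sigma2_e),
               grid[["ll"]] - 1e-6)
  }
})

test_that("pure-noise phenotypes give near-zero PVE", {
  pves <- sapply(1:5, function(r) {
    p <- simulate_genotype_matrix(150, 1000, 0, c(0.05, 0.5), 0, 3,
                                  seed = 90 + r)
    ph <- simulate_phenotype(p, 0, 0, seed = 190 + r)
    fit_single_component(ph$phenotype, compute_kinship(p))$pve[["g"]]
  })
  expect_lt(mean(pves), 0.1)
})

test_that("fits are shift-invariant and scale-equivariant", {
  p <- simulate_genotype_matrix(120, 800, 0, c(0.05, 0.5), 0, 3, seed = 95)
  ph <- simulate_phenotype(p, 0.5, 0, seed = 96)
  G <- compute_kinship(p)
  f1 <- fit_single_component(ph$phenotype, G)
  f2 <- fit_single_component(ph$phenotype + 100, G)
  expect_equal(f1$pve, f2$pve, tolerance = 1e-6)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-5)
  f3 <- fit_single_component(3 * ph$phenotype, G)
  expect_equal(f3$sigma2[["g"]], 9 * f1$sigma2[["g"]], tolerance = 1e-3)
  expect_equal(f3$pve, f1$pve, tolerance = 1e-6)
})

test_that("two-component PVEs follow the composite-model proportions", {
  p <- simulate_genotype_matrix(200, 800, 200, c(0.05, 0.5), 0, 9, seed = 97)
  ph <- simulate_phenotype(p, 0.35, 0.25, seed = 98)
  f <- fit_two_component(ph$phenotype, compute_kinship(p, "SNP"),
                         compute_kinship(p, "SV"))
  tot <- sum(f$sigma2) + f$sigma2_e
  expect_equal(f$pve[["snp"]], f$sigma2[["u1"]] / tot)
  expect_equal(f$pve[["sv"]], f$sigma2[["u2"]] / tot)
  expect_true(all(f$sigma2 >= 0) && f$sigma2_e >= 0)
  expect_lte(sum(f$pve), 1)
  expect_true(f$converged)
})

test_that("a null SV component collapses the composite fit to the single fit", {
  p <- simulate_genotype_matrix(150, 800, 0, c(0.05, 0.5), 0, 3, seed = 99)
  ph <- simulate_phenotype(p, 0.4, 0, seed = 100)
  G <- compute_kinship(p)
  single <- fit_single_component(ph$phenotype, G)
  zero <- matrix(0, 150, 150)
  both <- suppressWarnings(fit_two_component(ph$phenotype, unclass(G), zero))
  expect_equal(both$sigma2[["u1"]], single$sigma2[["g"]], tolerance = 1e-3)
  expect_equal(both$sigma2_e, single$sigma2_e, tolerance = 1e-3)
  expect_equal(both$pve[["snp"]], single$pve[["g"]], tolerance = 1e-3)
})

test_that("collinear kinships trigger a diagnostic warning", {
  p <- simulate_genotype_matrix(80, 800, 0, c(0.05, 0.5), 0, 2, seed = 101)
  ph <- simulate_phenotype(p, 0.4, 0, seed = 102)
  G <- compute_kinship(p)
  expect_warning(fit_two_component(ph$phenotype, G, G), "collinear")
})

test_that("degenerate phenotypes are rejected", {
  G <- diag(10)
  expect_error(fit_single_component(rep(1, 10), G), "zero variance")
  expect_error(fit_two_component(rep(0, 10), G, G), "zero variance")
})
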