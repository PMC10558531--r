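test_that("no planted SVs means every haplotype equals the reference", {
  sim <- simulate_pangenome_haplotypes(5000, 3, 0, seed = 1)
  expect_equal(nrow(sim$variants), 0)
  g <- build_graph(sim$reference, sim$variants, samples = sim$samples)
  for (s in sim$samples)
    expect_identical(unname(spell_walk(g, s)), unname(sim$reference))
})

test_that("a single 332 bp insertion lengthens its carrier by 332 bp", {
  sim <- simulate_pangenome_haplotypes(
    10000, 8, 1, sv_length_range = c(332, 332), multiallelic_fraction = 0,
    seed = 4, type_weights = c(insertion = 1, deletion = 0, divergent = 0))
  tr <- sim$truth$planted_svs
  expect_identical(tr$sv_type, "biallelic_insertion")
  carriers <- tr$carriers[[1]][[1]]
  g <- build_graph(sim$reference, sim$variants, samples = sim$samples)
  for (s in sim$samples) {
    expected <- 10000 + if (s %in% carriers) 332 else 0
    expect_equal(nchar(spell_walk(g, s)[["chr1"]]), expected)
  }
})

test_that("the haplotype simulator is byte-identical under a fixed seed", {
  a <- simulate_pangenome_haplotypes(50000, 6, 40, c(50, 500), 0.2, seed = 77)
  b <- simulate_pangenome_haplotypes(50000, 6, 40, c(50, 500), 0.2, seed = 77)
  expect_identical(a, b)
  c <- simulate_pangenome_haplotypes(50000, 6, 40, c(50, 500), 0.2, seed = 78)
  expect_false(identical(a$reference, c$reference))
})

test_that("planted SVs are non-overlapping, typed and carried consistently", {
  sim <- simulate_pangenome_haplotypes(100000, 8, 30, c(50, 800), 0.25,
                                       seed = 12)
  tr <- sim$truth$planted_svs
  expect_equal(nrow(tr), 30)
  # non-overlap with a gap on the reference
  ends <- tr$ref_start + nchar(tr$ref_allele)
  expect_true(all(tr$ref_start[-1] > ends[-nrow(tr)]))
  # allele content and carriers
  for (i in seq_len(nrow(tr))) {
    alts <- tr$alt_alleles[[i]]
    carriers <- tr$carriers[[i]]
    expect_true(all(grepl("^[ACGT]*$", alts)))
    expect_false(any(alts == tr$ref_allele[i]))
    expect_true(all(lengths(carriers) >= 1))
    expect_equal(anyDuplicated(unlist(carriers)), 0)
    if (tr$sv_type[i] == "multiallelic") expect_gte(length(alts), 2)
    else expect_length(alts, 1)
  }
  expect_error(
    simulate_pangenome_haplotypes(1000, 4, 50, c(400, 400), 0, seed = 1),
    "reference_length|place")
})

test_that("pangene simulator plants the requested class structure", {
  allcore <- simulate_pangene_matrix(5, 10, 0, 0, 0, seed = 2)
  expect_true(all(allcore$matrix == 1))
  expect_equal(dim(allcore$matrix), c(10, 5))

  sim <- simulate_pangene_matrix(32, 0, 0, 0, 5, seed = 3)
  expect_true(all(rowSums(sim$matrix) == 1))

  expect_error(simulate_pangene_matrix(2, 0, 3, 0, 0, seed = 1), "band")
})

test_that("genotype simulator controls missingness and realized MAF", {
  p <- simulate_genotype_matrix(60, 100, 20, c(0.1, 0.4), 0, 1, seed = 5)
  expect_false(anyNA(p$genotypes))
  expect_true(all(p$genotypes %in% c(0, 2)))
  maf <- panel_maf(p)
  expect_true(all(maf >= 0.1 - 1e-12 & maf <= 0.4 + 1e-12))

  pm <- simulate_genotype_matrix(60, 100, 20, c(0.1, 0.4), 0.2, 1, seed = 5)
  expect_gt(mean(is.na(pm$genotypes)), 0.15)
  expect_lt(mean(is.na(pm$genotypes)), 0.25)
  expect_error(
    simulate_genotype_matrix(60, 10, 0, missing_rate = 1, seed = 1),
    "missing_rate")
})

test_that("subpopulation structure shows up in the kinship matrix", {
  # panmictic: off-diagonals concentrate near zero
  p1 <- simulate_genotype_matrix(80, 2000, 0, c(0.05, 0.5), 0, 1, seed = 8)
  G1 <- compute_kinship(p1)
  off1 <- G1[lower.tri(G1)]
  expect_lt(abs(mean(off1)), 0.05)
  expect_lt(sd(off1), 0.1)
  # two subpopulations: within-group kinship exceeds between-group
  p2 <- simulate_genotype_matrix(80, 2000, 0, c(0.05, 0.5), 0, 2, seed = 9)
  G2 <- compute_kinship(p2)
  same <- outer(p2$subpop, p2$subpop, "==")
  within <- mean(G2[lower.tri(G2) & same])
  between <- mean(G2[lower.tri(G2) & !same])
  expect_gt(within, between)
})

test_that("phenotype simulator hits its variance targets and is seeded", {
  p <- simulate_genotype_matrix(300, 500, 100, c(0.05, 0.5), 0, 1, seed = 10)
  ph <- simulate_phenotype(p, 0.4, 0.2, seed = 11)
  expect_identical(ph$phenotype,
                   simulate_phenotype(p, 0.4, 0.2, seed = 11)$phenotype)
  expect_equal(ph$truth$true_pve, c(snp = 0.4, sv = 0.2))
  expect_true(all(ph$truth$causal_variants$id %in% p$variants$id))
  # realized variance close to 1 (terms scaled exactly, cross terms small)
  expect_equal(var(ph$phenotype), 1, tolerance = 0.15)

  noise <- simulate_phenotype(p, 0, 0, seed = 12)
  expect_equal(var(noise$phenotype), 1, tolerance = 1e-10)
  expect_error(simulate_phenotype(p, -0.1, 0, seed = 1), "non-negative")
  expect_error(simulate_phenotype(p, 0.7, 0.4, seed = 1), "<= 1")
})
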