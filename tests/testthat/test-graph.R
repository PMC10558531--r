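ref1 <- c(chr1 = "ACGTACGTACGTACGTACGTACGTACGTACGT")  # 32 bp

test_that("a variant-free graph is a single chain with identical walks", {
  v <- data.frame(chrom = character(0), start = integer(0),
                  ref_allele = character(0), alt_allele = character(0),
                  sample = character(0))
  g <- build_graph(ref1, v, samples = c("S1", "S2", "S3"))
  expect_equal(graph_stats(g)$n_segments, 1)
  expect_equal(graph_stats(g)$nonref_length, 0)
  for (s in c("S1", "S2", "S3"))
    expect_identical(g$walks[[s]], g$walks[[g$reference_walk]])
})

test_that("one insertion carried by one sample adds one segment, two links", {
  ins <- paste(rep("A", 100), collapse = "")
  v <- data.frame(chrom = "chr1", start = 9, ref_allele = "",
                  alt_allele = ins, sample = "S1")
  g <- build_graph(ref1, v, samples = c("S1", "S2"))
  st <- graph_stats(g)
  expect_equal(st$n_segments, 3)              # two reference parts + insert
  expect_equal(st$nonref_length, 100)
  expect_equal(st$n_links, 3)                 # ref join + two insert links
  expect_equal(st$per_sample$nonref_length, c(100, 0))
})

test_that("samples sharing an allele share one non-reference segment", {
  v <- data.frame(chrom = "chr1", start = c(9, 9), ref_allele = "",
                  alt_allele = "GGGG", sample = c("S1", "S2"))
  g <- build_graph(ref1, v)
  nonref <- names(g$segments)[g$segment_origin == "non-reference"]
  expect_length(nonref, 1)
  expect_identical(g$walks$S1, g$walks$S2)
})

test_that("walk spelling equals direct string substitution of variants", {
  for (seed in 1:5) {
    sim <- simulate_pangenome_haplotypes(20000, 5, 12, c(20, 300), 0.2,
                                         seed = seed)
    g <- build_graph(sim$reference, sim$variants, samples = sim$samples)
    validate_graph(g)
    expect_identical(spell_walk(g, g$reference_walk)[["chr1"]],
                     unname(sim$reference))
    for (s in sim$samples) {
      rows <- sim$variants[sim$variants$sample == s, , drop = FALSE]
      expect_identical(spell_walk(g, s)[["chr1"]],
                       apply_variants_string(unname(sim$reference), rows))
    }
  }
})

test_that("multi-chromosome references are handled per chromosome", {
  ref <- c(chrA = "AAAACCCCGGGGTTTTAAAA", chrB = "TTTTGGGGCCCCAAAATTTT")
  v <- data.frame(chrom = c("chrA", "chrB"), start = c(5, 9),
                  ref_allele = c("CCCC", ""), alt_allele = c("", "AAA"),
                  sample = "S1")
  g <- build_graph(ref, v, samples = c("S1", "S2"))
  expect_identical(spell_walk(g, "S1", "chrA")[["chrA"]],
                   "AAAAGGGGTTTTAAAA")
  expect_identical(spell_walk(g, "S1", "chrB")[["chrB"]],
                   "TTTTGGGGAAACCCCAAAATTTT")
  expect_identical(spell_walk(g, "S2"), stats::setNames(unname(ref), names(ref)))
})

test_that("inconsistent variant tables are rejected with sample and position", {
  v_bad_ref <- data.frame(chrom = "chr1", start = 5, ref_allele = "TTTT",
                          alt_allele = "", sample = "S9")
  expect_error(build_graph(ref1, v_bad_ref), "S9.*chr1:5|mismatch")
  v_oob <- data.frame(chrom = "chr1", start = 31, ref_allele = "GTAC",
                      alt_allele = "", sample = "S1")
  expect_error(build_graph(ref1, v_oob), "flank")
  v_same <- data.frame(chrom = "chr1", start = 5, ref_allele = "ACGT",
                       alt_allele = "ACGT", sample = "S1")
  expect_error(build_graph(ref1, v_same), "not a variant")
  v_overlap <- data.frame(chrom = "chr1", start = c(5, 7),
                          ref_allele = c("ACGT", "GTAC"),
                          alt_allele = c("", ""), sample = "S1")
  expect_error(build_graph(ref1, v_overlap), "overlap")
})

test_that("graph growth is non-decreasing for any addition order", {
  sim <- simulate_pangenome_haplotypes(30000, 6, 10, c(50, 400), 0.2,
                                       seed = 19)
  for (ord_seed in 1:3) {
    set.seed(ord_seed)
    ord <- sample(sim$samples)
    gr <- pan_graph_growth(sim$reference, sim$variants, ord)
    expect_true(all(diff(gr$total_length) >= 0))
    expect_true(all(diff(gr$nonref_length) >= 0))
  }
  # no variants: flat growth at reference length
  flat <- pan_graph_growth(sim$reference,
                           sim$variants[0, ], sim$samples[1:3])
  expect_true(all(flat$total_length == nchar(sim$reference)))
  expect_true(all(flat$nonref_length == 0))
})
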