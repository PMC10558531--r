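# A small SV set built through the real pipeline, positioned for the
# overlap cases below.
ann_fixture <- local({
  ref <- c(chr1 = paste(rep("ACGTTGCA", 2500), collapse = ""))  # 20 kb
  ins <- paste(rep("T", 332), collapse = "")
  del_ref <- substr(ref, 12001, 12300)
  v <- data.frame(chrom = "chr1",
                  start = c(4500, 12001),
                  ref_allele = c("", del_ref),
                  alt_allele = c(ins, ""),
                  sample = "S1")
  g <- build_graph(ref, v, samples = c("S1", "S2"))
  list(svs = call_svs(detect_bubbles(g)), ref = ref)
})

test_that("an insertion 500 bp upstream of a + strand TSS hits the promoter", {
  svs <- ann_fixture$svs
  genes <- data.frame(gene_id = "HPCA1", chrom = "chr1",
                      start = 5000, end = 7000, strand = "+")
  ov <- sv_gene_overlap(svs, genes)
  hit <- ov$overlaps[ov$overlaps$gene_id == "HPCA1", ]
  expect_equal(hit$region, "promoter")
  expect_equal(hit$sv_id, "chr1:4499")
  expect_equal(ov$fraction_affected, 1)
})

test_that("a gene inside a deletion is a gene_body (and CDS) overlap", {
  svs <- ann_fixture$svs
  genes <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = 12050, end = 12250, strand = "+")
  cds <- data.frame(gene_id = "g1", chrom = "chr1",
                    start = 12100, end = 12200)
  ov <- sv_gene_overlap(svs, genes, cds = cds)
  expect_setequal(ov$overlaps$region[ov$overlaps$gene_id == "g1"],
                  c("gene_body", "CDS", "promoter"))
})

test_that("minus-strand promoters extend downstream in reference coordinates", {
  svs <- ann_fixture$svs
  # TSS of a - strand gene at its end coordinate; promoter = [end+1, end+2000]
  genes <- data.frame(gene_id = c("gm", "gfar"), chrom = "chr1",
                      start = c(2000, 15000), end = c(4000, 16000),
                      strand = "-")
  ov <- sv_gene_overlap(svs, genes)
  expect_true("gm" %in% ov$genes_affected)       # 4499 within 4001..6000
  expect_false("gfar" %in% ov$genes_affected)
  expect_equal(ov$fraction_affected, 0.5)
})

test_that("disjoint SVs leave genes unaffected and truncation warns", {
  svs <- ann_fixture$svs
  genes <- data.frame(gene_id = "far", chrom = "chr1",
                      start = 18000, end = 19000, strand = "+")
  ov <- sv_gene_overlap(svs, genes)
  expect_equal(nrow(ov$overlaps), 0)
  expect_equal(ov$fraction_affected, 0)
  near_start <- data.frame(gene_id = "ns", chrom = "chr1",
                           start = 100, end = 600, strand = "+")
  expect_warning(sv_gene_overlap(svs, near_start), "truncated")
})

test_that("TE flagging respects the coverage threshold", {
  svs <- ann_fixture$svs
  expect_false(any(sv_te_overlap(svs, NULL)$te_flag))
  ins_id <- sprintf("chr1:%d:1", svs$pos[1])
  # fully covered insertion allele -> flagged with its class
  te_full <- data.frame(chrom = ins_id, start = 1, end = 332, class = "LTR")
  full <- sv_te_overlap(svs, te_full)
  expect_true(full$te_flag[1])
  expect_equal(full$te_class[1], "LTR")
  expect_false(full$te_flag[2])
  # 40% coverage: below the 0.5 default, above a 0.3 threshold
  te_part <- data.frame(chrom = ins_id, start = 1,
                        end = round(0.4 * 332), class = "TIR")
  expect_false(sv_te_overlap(svs, te_part)$te_flag[1])
  expect_true(sv_te_overlap(svs, te_part, min_fraction = 0.3)$te_flag[1])
  # reference-footprint annotation flags the deletion
  te_ref <- data.frame(chrom = "chr1", start = 12001, end = 12300,
                       class = "Helitron")
  del <- sv_te_overlap(svs, te_ref)
  expect_true(del$te_flag[2])
  expect_equal(del$te_class[2], "Helitron")
})

test_that("density windows tile chromosomes and hotspots follow the quantile", {
  svs <- ann_fixture$svs
  d0 <- sv_density_hotspots(sv_set(list()), c(chr1 = 2e6))
  expect_true(all(d0$sv_count == 0))
  expect_false(any(d0$is_hotspot))

  # cluster all SVs of a sparse genome into one window
  sim <- simulate_pangenome_haplotypes(60000, 4, 10, c(50, 100), 0,
                                       seed = 51)
  g <- build_graph(sim$reference, sim$variants, samples = sim$samples)
  s <- call_svs(detect_bubbles(g))
  d <- sv_density_hotspots(s, c(chr1 = 2e6), window = 60000, step = 60000,
                           top_fraction = 0.05)
  expect_equal(sum(d$sv_count), nrow(s))
  expect_true(all(d$is_hotspot == (d$sv_count >= attr(d, "threshold") &
                                     d$sv_count > 0)))
  expect_true(sum(d$is_hotspot) >= 1)
  expect_true(all(which(d$is_hotspot) %in% which(d$sv_count > 0)))
  # windows tile at the step size and end within the chromosome
  expect_true(all(diff(d$start) == 60000))
  expect_true(all(d$end <= 2e6))
})

test_that("quantile hotspots are invariant to doubling all counts", {
  set.seed(7)
  svs <- sv_set(lapply(sort(sample(1e6, 200)), function(p) list(
    chrom = "chr1", pos = p, end = p, anchor_base = "A", ref_allele = "",
    sv_type = "biallelic_insertion", sv_length = 60L,
    source = NA_character_, sink = NA_character_,
    alt_alleles = "A", carriers = list("S1"),
    ref_carriers = character(0))))
  d1 <- sv_density_hotspots(svs, c(chr1 = 1.2e6))
  doubled <- rbind(svs, svs)
  class(doubled) <- class(svs)
  d2 <- sv_density_hotspots(doubled, c(chr1 = 1.2e6))
  expect_equal(d2$sv_count, 2L * d1$sv_count)
  expect_equal(d1$is_hotspot, d2$is_hotspot)
})
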