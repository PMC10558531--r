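# pansv

Graph pan-genome structural-variant calling and SNP/SV variance
partitioning for inbred plant panels.

## What it is for

Selfing species such as *Arabidopsis thaliana* come as panels of
effectively homozygous accessions whose genomes differ by structural
variants (SVs, sequence differences ≥ 50 bp) as well as SNPs. `pansv`
covers the SV side of a pan-genome analysis end to end:

* **Graph pan-genome.** `build_graph()` turns a reference plus
  per-sample variant tables into a reference-backbone sequence graph
  (segments, links, one walk per sample). `detect_bubbles()` finds the
  stretches where walks diverge; `call_svs()` types each bubble as a
  biallelic insertion / deletion / divergent site (one non-reference
  path) or a multiallelic site (several), keeps variants with maximum
  allele length ≥ 50 bp, and `genotype_walks()` calls every sample at
  every site. GFA 1.0 and VCF 4.2 round trips are lossless.
* **Occurrence classes.** `classify_gene_clusters()` /
  `classify_te_families()` split gene clusters and TE families into
  core / softcore / dispensable / private (TEs: core / variable /
  rare) by the number of genomes they occur in, with saturation curves
  (`pan_core_curve()`) and LTR insertion-time dating
  (`ltr_insertion_time()`, T = K / 2μ).
* **Annotation.** `sv_gene_overlap()` (gene body, CDS, 2 kb promoter),
  `sv_te_overlap()`, and `sv_density_hotspots()` (50 kb windows, 20 kb
  step, top-5% threshold).
* **QC, LD and association.** `filter_panel()` (missingness and MAF
  rules), `ld_r2()` and `tag_svs_by_snps()` (which SVs a SNP array
  would see, at LD r² > 0.6), and `lmm_assoc()` — the standard
  one-kinship mixed-model scan with Bonferroni thresholds.
* **Variance partitioning.** `compute_kinship()` builds standardized
  GRMs from SNPs and SVs separately; `fit_single_component()` fits
  y = μ + Zu + e with ZZ' = G by REML and reports
  PVE = σ²g / (σ²g + σ²e); `fit_two_component()` fits the composite
  model y = μ + Z₁u₁ + Z₂u₂ + e and reports
  PVE_snp = σ²u₁ / (σ²u₁ + σ²u₂ + σ²e) and the SV analogue — the
  quantity behind "how much of this trait do SVs explain that SNPs do
  not".
* **Synthetic data.** `simulate_pangenome_haplotypes()`,
  `simulate_pangene_matrix()`, `simulate_genotype_matrix()` and
  `simulate_phenotype()` generate every input above with known ground
  truth (planted SVs, planted classes, planted variance fractions), so
  the whole pipeline is testable without any external data.

## Worked example

```r
library(pansv)

# a 200 kb reference, 8 ecotypes, 20 planted SVs of all four types
sim <- simulate_pangenome_haplotypes(200000, 8, 20, c(50, 2000),
                                     multiallelic_fraction = 0.15, seed = 42)
g   <- build_graph(sim$reference, sim$variants, samples = sim$samples)
g
#> sequence_graph: 53 segments, 77 links, 9 walks (reference: REF)
#>   total 213516 bp, non-reference 13516 bp

svs <- call_svs(detect_bubbles(g), min_len = 50)
svs
#> sv_set: 20 structural variants
#>  biallelic_deletion biallelic_divergent biallelic_insertion        multiallelic
#>                  11                   4                   2                   3
```

All 20 planted SVs come back with exact anchors, alleles, types and
carriers (the test suite asserts precision = recall = 1). On the
quantitative side, a panel with planted variance fractions:

```r
panel <- simulate_genotype_matrix(500, 2000, 300, n_subpops = 9, seed = 43)
ph    <- simulate_phenotype(panel, pve_snp = 0.4, pve_sv = 0.2, seed = 44)
fit_two_component(ph$phenotype,
                  compute_kinship(panel, "SNP"),
                  compute_kinship(panel, "SV"))
#> REML fit (two-component): mu = 0.01032, sigma2_e = 0.3595
#>   sigma2_u1 = 0.3697  (PVE_snp = 0.419)
#>   sigma2_u2 = 0.1532  (PVE_sv = 0.174)
```

The composite REML fit attributes 41.9% of the phenotypic variance to
the SNP kinship and 17.4% to the SV kinship — the planted fractions
were 40% and 20%, and averaging such fits over replicate panels
recovers them to within a few points (see the methods vignette for the
experiment design and its Monte-Carlo margins).

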