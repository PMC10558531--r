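---
title: "Graph pan-genome SV calling and SNP/SV variance partitioning with pansv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph pan-genome SV calling and SNP/SV variance partitioning with pansv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pansv)
```

## The problem

Inbred plant accessions — *Arabidopsis thaliana* ecotypes are the
motivating case — differ not only by SNPs but by structural variants
(SVs, here sequence differences of at least 50 bp). `pansv` implements
the SV side of a pan-genome analysis for such selfing, effectively
homozygous material: representing many haplotypes against one reference
as a sequence graph, calling and classifying SVs from the graph's
bubbles, classifying gene and TE content by occurrence across genomes,
annotating SVs against gene models, and quantifying how much phenotypic
variance SVs explain relative to SNPs under mixed models.

Everything is exercisable on synthetic data with known ground truth,
so every stage has an exact or statistical oracle.

## The sequence graph and bubble model

`build_graph()` constructs a *reference-backbone* graph from a
per-sample variant table: the reference is split into segments at the
union of all variant breakpoints; each distinct alternate allele at a
site becomes one shared non-reference segment; each sample's walk
spells its haplotype exactly (the spelling invariant
`spell_walk(g, s) == haplotype(s)` is tested property-style).
Construction is coordinate-driven rather than alignment-driven: the
upstream problem of aligning assemblies is out of scope, which isolates
the bubble and SV logic from any particular aligner.

A **bubble** is the stretch between two backbone anchors where walks
diverge into two or more spelled sequences. `detect_bubbles()` locates
each walk's deviations from the backbone, merges deviations whose
reference intervals overlap *or touch* (closed-interval semantics), and
anchors each merged interval at the nearest flanking reference
segments. Merging means nested or coinciding alternation is reported as
a single multiallelic bubble rather than a decomposition into nested
bubbles — one site, one record, which matches how multiallelic SVs are
counted downstream. The detector is checked against a brute-force
enumerator that examines every anchor pair traversed by all walks and
keeps minimal pairs with two or more distinct spelled interiors.

`call_svs()` types each bubble: one non-reference allele is biallelic —
insertion (empty reference interior), deletion (empty alternate), or
divergent (both non-empty; inversions and other balanced replacements
fall here) — and two or more non-reference alleles are multiallelic.
**SV length is the maximum allele length** (reference included); this
single definition drives both the 50 bp filter and the emitted `SVLEN`.
The choice matters only for divergent and multiallelic sites, where
reference and alternate lengths differ; maximum length is the
conservative reading (a site is kept if *any* allele is structural).
Coordinates are 0-based half-open internally and exported VCF-style:
`POS` is the base before the bubble interior and alleles carry that
anchor base, which represents empty alleles losslessly.

All walks are forward-strand; translocations, duplications and cyclic
graphs are out of scope.

## Occurrence classes, saturation and LTR dating

`classify_gene_clusters()` assigns each gene cluster a class from its
occupancy count across N genomes: core (all N), softcore, dispensable,
private (exactly 1). At N = 32 the bands are 32 / 26–31 / 2–25 / 1; for
other N the softcore lower edge generalizes as `ceiling(0.8125 N)`,
which reproduces the N = 32 bands exactly and degrades gracefully
(at N = 2 only core and private remain). TE families use core /
variable (6 to N−1) / rare (1–5). Bands are user-overridable via
`occurrence_scheme()`; occupancy counts presence of at least one
member, not copy number.

`pan_core_curve()` samples random genome orderings (default 30
repeats) and reports pan and core sizes per subset size with medians
and quartiles, the statistics drawn in saturation boxplots. Under
independent presence with probability `p`, mean pan(k) has the closed
form `F (1 − (1−p)^k)`, which the tests verify within Monte-Carlo
error.

`ltr_insertion_time()` dates an LTR retrotransposon from the
divergence K of its two terminal repeats as `T = K / (2 mu)` — the
repeats are identical on insertion and diverge at the neutral rate
afterwards. The default rate, 7e-9 substitutions per site per year, is
the value standardly used for *A. thaliana* TE dating.

## SV annotation

`sv_gene_overlap()` intersects SV reference footprints with gene
bodies, CDS intervals and promoters (2 kb upstream of the TSS;
downstream in reference coordinates for minus-strand genes; truncated
at chromosome start with a warning). A pure insertion has a zero-length
reference footprint, so its *anchor point* is used for intersection —
the predicate had to be defined somewhere, and the anchor point is the
only reference coordinate an insertion has. `sv_te_overlap()` flags an
SV as TE-derived when annotation covers at least half (configurable) of
an allele, either on the reference footprint or on the insertion
allele's own coordinates. `sv_density_hotspots()` counts SV anchors in
50 kb windows sliding by 20 kb and flags the top 5% of window counts
genome-wide (one joint threshold across chromosomes, zero-count windows
never flagged).

## Genotype panels, QC and LD tagging

Panels are dosage matrices over `{0, 2, NA}` — the homozygous coding
natural for selfing species. `filter_panel()` applies, in one
deterministic pass, variant missingness, MAF and then sample
missingness thresholds; the SNP defaults (0.1 / 0.03 / 0.1) mirror
common plink practice and the SV setting (0.5 / 0.05) the usual SV
filter. The MAF rule removes variants *below* the threshold; the
occasionally seen phrasing "MAF above 0.05" for SV filters describes
the same operation from the keep side and would be self-defeating read
literally. `ld_r2()` is the squared Pearson correlation of dosages
over pairwise-complete samples; `tag_svs_by_snps()` reports, per SV,
the maximum r² against SNPs within a window (default ±100 kb — the
window is a free parameter; genome-wide LD would conflate linkage with
structure) and the tagging curve across cutoffs, with 0.6 as the
default tagging threshold.

## Variance partitioning (the mixed models)

With kinship `G = W W' / m` from column-standardized dosages
(GCTA-style standardized GRM; missing dosages mean-imputed — the
formula had to be fixed somewhere and this is the field standard), the
single-component model is

    y = mu + Z u + e,   Z Z' = G,   u ~ N(0, I sigma2_g),

fitted by REML, and the variance explained is the intraclass
correlation `sigma2_g / (sigma2_g + sigma2_e)`. The two-component
model adds independent SNP- and SV-kinship effects,

    y = mu + Z1 u1 + Z2 u2 + e,

and reports `PVE_snp = sigma2_u1 / (sigma2_u1 + sigma2_u2 + sigma2_e)`
and the SV analogue. Both fits are offered because per-trait
comparisons can be read either off the separate single-kinship fits or
off the joint fit; the two disagree when kinships are correlated, and
the joint fit is the one that partitions a single phenotypic variance.

Numerics: the single-component restricted likelihood is profiled over
the variance ratio on an eigendecomposition of G (one bounded 1-D
optimization; non-negativity automatic; the ratio-zero boundary is
checked explicitly). The two-component fit maximizes the restricted
log-likelihood directly over the three variances with L-BFGS-B,
analytic gradients `dl/ds2_k = -1/2 [tr(P G_k) - y'P G_k P y]`, lower
bounds at zero, and a relative function tolerance of about 1e-7 with at
most 200 iterations; an all-zero kinship pins its component at zero
rather than leaving it unidentifiable, and kinship correlation above
0.99 triggers a collinearity warning. `kinship_design()` returns Z
with `Z Z' = G` by Cholesky, falling back to an eigenfactorization
with negative eigenvalues clipped at 1e-10 for rank-deficient G.
Standard errors of variance components are not computed.

## Association

`lmm_assoc()` is the standard one-kinship mixed-model scan: null
variance components estimated once and reused for all variants, each
variant tested by GLS in the whitened space with a Wald test. This is
the EMMAX/MLMA convention; per-variant re-estimation buys little at
GWAS scale and is not what the reference tools do. Phenotypes can be
standardized first (`standardize_phenotype()`); p-values are invariant
to that. `significance_threshold()` is Bonferroni with an optional
effective-test-count override — printed genome-wide thresholds in the
literature rarely match naive Bonferroni on the stated test counts, so
the effective count is a parameter, not a constant.

## What the synthetic data emulates — and what it does not

`simulate_pangenome_haplotypes()` plants non-overlapping insertions,
deletions, divergent and multiallelic SVs (2–3 alternate alleles with
disjoint carrier sets) into a uniform-random reference and spells each
sample's haplotype exactly. Planted SVs are separated by at least one
reference base, so each maps to exactly one bubble; overlapping-SV
behaviour is intentionally unspecified and untested. The reference has
no repeat structure, so the simulator cannot probe alignment ambiguity
— irrelevant here because construction is coordinate-driven, but it
means a pass says nothing about aligner-induced errors on real
assemblies.

`simulate_genotype_matrix()` draws, per variant, an alternate-carrier
count uniformly over the counts whose frequency lies in the requested
MAF range — realized MAF is therefore in-range *by construction* — and
allocates carriers across subpopulations with Dirichlet-weighted
probabilities. The variance-partition and GWAS experiments use nine
subpopulations, mirroring the roughly nine ancestry groups described
for worldwide *A. thaliana* collections; with unrelated samples
instead, the SNP-kinship component is nearly unidentifiable at the
scales used here (the sampling error of an h² estimate grows like
sqrt(2 m)/n), which is a property of the estimator, not of the code.
Linkage disequilibrium between neighbouring variants is *not*
simulated (each variant draws carriers independently), so LD-tagging
fractions on synthetic panels reflect structure-induced correlation
only and are far below what real, physically linked panels show.

`simulate_phenotype()` builds `y = mu + g_snp + g_sv + e` from normal
effects on standardized causal dosages, rescaling each term so the
realized variance fractions match the requested PVEs; the composite
mixed model above is exactly its generative direction. Real phenotypes
are measured, not generated; the simulator is a test harness, and
recovery results certify the estimator under its own model, not the
biology.

## Problem sizes used by the checks

The bundled checks run, per invocation: one 500 kb / 8-sample / 40-SV
recovery experiment; 300–1000 random graphs (at most 30 segments)
against the brute-force bubble enumerator; 50–100 occurrence-matrix
round trips at N = 32; saturation curves on 16-genome matrices; twenty
500-sample × 2300-variant REML recovery replicates per setting; about
22,000 null association tests and 50–100 power replicates. These sizes
keep each stage's Monte-Carlo error well inside its acceptance margin
while completing in minutes on one core.

## Known limitations

No alignment, read mapping, imputation or phasing; no cyclic or
reverse-strand graph features; SV length of divergent sites is the
maximum-allele convention (a minimum-allele reading would drop a few
borderline sites); hotspot thresholds are genome-wide quantiles, not
per-chromosome; REML standard errors are not provided; the two-kinship
fit can be slow beyond a few thousand samples (dense n × n algebra per
likelihood evaluation).
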