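Package: pansv
Title: Graph Pan-Genome Structural Variant Calling and Variance Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds reference-backbone sequence graphs from per-sample
    haplotype variant tables, detects bubbles and calls classified
    structural variants (insertions, deletions, divergent alleles,
    multiallelic sites) with per-sample genotypes; classifies pan-gene
    and pan-TE occurrence (core/softcore/dispensable/private) and
    computes pan/core saturation curves and LTR insertion times;
    intersects SVs with gene models, promoters and TE annotations and
    finds SV density hotspots; performs genotype quality control,
    linkage-disequilibrium tagging of SVs by SNPs, REML variance
    partitioning between SNP and SV kinships under one- and
    two-random-effect mixed models, and mixed-model association
    scans. Ships a synthetic-data generator that produces every input
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
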