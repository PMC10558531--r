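# Hand-enumerated toy QC panel: 10 samples x 5 variants; v2 is 60%
# missing and v4 is monomorphic (with 10 homozygous samples the smallest
# non-zero MAF is 0.1, so "below the MAF cut-off" means monomorphic).
toy_qc_panel <- function() {
  g <- matrix(0, 10, 5)
  g[1:5, 1] <- 2                      # v1: MAF 0.5
  g[1:6, 2] <- NA                     # v2: 60% missing
  g[1:3, 3] <- 2                      # v3: MAF 0.3
  # v4: monomorphic (all reference)   # dropped by the MAF rule
  g[1, 5] <- 2                        # v5: MAF 0.1
  variants <- data.frame(id = paste0("v", 1:5), chrom = "1",
                         pos = c(100, 200, 300, 400, 500),
                         class = c("SNP", "SNP", "SNP", "SV", "SV"))
  genotype_panel(g, variants)
}
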