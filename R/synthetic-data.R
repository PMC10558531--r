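#' Simulate a pan-genome: reference plus haplotypes carrying planted SVs
#'
#' Generates a random reference chromosome and a set of inbred sample
#' haplotypes that differ from it by planted structural variants of four
#' kinds: insertion (empty reference allele), deletion (empty alternate
#' allele), divergent (both alleles non-empty and different) and
#' multiallelic (two or three alternate alleles with disjoint carrier
#' sets). Planted SVs never overlap on the reference and are separated
#' by at least one reference base, so each maps to exactly one bubble in
#' the downstream graph.
#'
#' @param reference_length Reference length in bp.
#' @param n_samples Number of sample haplotypes.
#' @param n_svs Number of SVs to plant.
#' @param sv_length_range Length range (bp) for each planted allele.
#' @param multiallelic_fraction Fraction of planted SVs that are
#'   multiallelic.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param chrom Chromosome name used throughout.
#' @param type_weights Named sampling weights for the biallelic types
#'   `insertion`, `deletion`, `divergent` (default equal).
#' @return A list with components:
#'   * `reference`: named character vector (one chromosome).
#'   * `variants`: `data.frame` with columns `chrom`, `start`, `ref_allele`,
#'     `alt_allele`, `sample` — one row per carried allele per sample
#'     (`start` is the 1-based position of the first affected reference
#'     base; for insertions, of the base before which the insertion sits).
#'   * `truth`: a `sim_truth` list recording every planted SV
#'     (`planted_svs` with anchor position, alleles, type, carriers) and
#'     the seed.
#' @examples
#' sim <- simulate_pangenome_haplotypes(20000, 4, 5, c(50, 200), 0.2, seed = 1)
#' table(sim$truth$planted_svs$sv_type)
#' @export
simulate_pangenome_haplotypes <- function(reference_length, n_samples, n_svs,
                                          sv_length_range = c(50, 2000),
                                          multiallelic_fraction = 0.1,
                                          seed, chrom = "chr1",
                                          type_weights = c(insertion = 1,
                                                           deletion = 1,
                                                           divergent = 1)) {
  stopifnot(reference_length >= 1, n_samples >= 1, n_svs >= 0,
            length(sv_length_range) == 2, sv_length_range[1] >= 1,
            sv_length_range[1] <= sv_length_range[2],
            multiallelic_fraction >= 0, multiallelic_fraction <= 1)
  if (n_svs > 0 && reference_length < 10 * sv_length_range[2])
    stop_pansv("reference_length must be >= 10 x the maximum SV length (%d < %d)",
               reference_length, 10 * sv_length_range[2])
  with_seed(seed, {
    reference <- stats::setNames(random_dna(1, reference_length), chrom)
    samples <- paste0("S", seq_len(n_samples))

    types <- character(0)
    if (n_svs > 0) {
      n_multi <- round(multiallelic_fraction * n_svs)
      bi <- sample(c("insertion", "deletion", "divergent"),
                   n_svs - n_multi, replace = TRUE,
                   prob = type_weights[c("insertion", "deletion",
                                         "divergent")])
      types <- sample(c(bi, rep("multiallelic", n_multi)))
    }

    # reference footprint per SV (0 for insertions)
    ref_len <- integer(n_svs)
    draw_len <- function(n) {
      if (n == 0) return(integer(0))
      lens <- seq(sv_length_range[1], sv_length_range[2])
      lens[sample.int(length(lens), n, replace = TRUE)]
    }
    ref_len[types %in% c("deletion", "divergent")] <-
      draw_len(sum(types %in% c("deletion", "divergent")))
    is_multi <- types == "multiallelic"
    # multiallelic sites get a reference footprint half the time
    multi_has_ref <- stats::runif(sum(is_multi)) < 0.5
    ref_len[is_multi][multi_has_ref] <- draw_len(sum(multi_has_ref))

    starts <- place_intervals(reference_length, ref_len, gap = 2L)

    planted <- vector("list", n_svs)
    rows <- vector("list", n_svs)
    for (i in seq_len(n_svs)) {
      rl <- ref_len[i]
      ref_allele <- if (rl == 0) "" else
        unname(substr(reference, starts[i], starts[i] + rl - 1L))
      n_alt <- if (types[i] == "multiallelic") {
        if (n_samples < 3)
          stop_pansv("multiallelic SVs need >= 3 samples (disjoint carrier sets plus a reference carrier)")
        if (n_samples == 3L) 2L else sample(2:3, 1)
      } else 1L
      alt <- character(n_alt)
      for (j in seq_len(n_alt)) {
        repeat {
          a <- switch(types[i],
            insertion = random_dna(1, draw_len(1)),
            deletion = "",
            divergent = random_dna(1, draw_len(1)),
            multiallelic = random_dna(1, draw_len(1)))
          if (a != ref_allele && !a %in% alt[seq_len(j - 1L)]) break
        }
        alt[j] <- a
      }
      # disjoint, non-empty carrier sets; at least one non-carrier kept
      # when possible so the site is polymorphic in the panel
      max_carriers <- max(n_alt, n_samples - 1L)
      n_carry <- if (n_alt == max_carriers) n_alt else
        sample(seq(n_alt, max_carriers), 1)
      carry <- sample(samples, n_carry)
      # first n_alt carriers pin one carrier per allele; the rest random
      alloc <- c(seq_len(n_alt),
                 if (n_carry > n_alt)
                   sample(seq_len(n_alt), n_carry - n_alt, replace = TRUE))
      carriers <- lapply(seq_len(n_alt), function(j) sort(carry[alloc == j]))
      planted[[i]] <- list(
        chrom = chrom, ref_start = starts[i],
        pos = starts[i] - 1L,          # anchor base before the interior
        ref_allele = ref_allele, alt_alleles = alt,
        sv_type = if (n_alt > 1) "multiallelic" else
          paste0("biallelic_", types[i]),
        sv_length = max(nchar(c(ref_allele, alt))),
        carriers = carriers
      )
      rows[[i]] <- do.call(rbind, lapply(seq_len(n_alt), function(j)
        data.frame(chrom = chrom, start = starts[i], ref_allele = ref_allele,
                   alt_allele = alt[j], sample = carriers[[j]],
                   stringsAsFactors = FALSE)))
    }
    variants <- if (n_svs == 0)
      data.frame(chrom = character(0), start = integer(0),
                 ref_allele = character(0), alt_allele = character(0),
                 sample = character(0))
    else do.call(rbind, rows)
    variants <- variants[order(variants$sample, variants$start), , drop = FALSE]
    rownames(variants) <- NULL

    truth <- sim_truth(
      planted_svs = planted_sv_table(planted),
      seed = seed
    )
    list(reference = reference, variants = variants, samples = samples,
         truth = truth)
  })
}

# Place n non-overlapping intervals of the given reference lengths,
# separated by >= `gap` bp and away from the chromosome ends.
place_intervals <- function(reference_length, ref_len, gap = 2L,
                            max_tries = 1000L) {
  n <- length(ref_len)
  if (n == 0) return(integer(0))
  for (try in seq_len(max_tries)) {
    # sample starts, then check pairwise separation after sorting
    ord <- order(ref_len, decreasing = TRUE)
    starts <- integer(n)
    taken_start <- integer(0); taken_end <- integer(0)
    ok <- TRUE
    for (i in ord) {
      lo <- 1L + gap
      hi <- reference_length - max(ref_len[i], 1L) - gap
      if (hi < lo) { ok <- FALSE; break }
      placed <- FALSE
      for (k in seq_len(50L)) {
        s <- sample.int(hi - lo + 1L, 1L) + lo - 1L
        e <- s + max(ref_len[i] - 1L, 0L)
        if (!any(s - gap <= taken_end & e + gap >= taken_start)) {
          starts[i] <- s
          taken_start <- c(taken_start, s); taken_end <- c(taken_end, e)
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(starts)
  }
  stop_pansv(paste0(
    "could not place %d non-overlapping SV intervals on a %d bp reference ",
    "(non-overlap constraint unsatisfiable after %d attempts)"),
    n, reference_length, max_tries)
}

planted_sv_table <- function(planted) {
  if (length(planted) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref_start = integer(0), ref_allele = character(0),
                      sv_type = character(0), sv_length = integer(0),
                      alt_alleles = I(list()), carriers = I(list())))
  d <- data.frame(
    chrom = vapply(planted, `[[`, "", "chrom"),
    pos = vapply(planted, `[[`, 0L, "pos"),
    ref_start = vapply(planted, `[[`, 0L, "ref_start"),
    ref_allele = vapply(planted, `[[`, "", "ref_allele"),
    sv_type = vapply(planted, `[[`, "", "sv_type"),
    sv_length = vapply(planted, `[[`, 0L, "sv_length"),
    stringsAsFactors = FALSE
  )
  d$alt_alleles <- I(lapply(planted, `[[`, "alt_alleles"))
  d$carriers <- I(lapply(planted, `[[`, "carriers"))
  d <- d[order(d$chrom, d$pos), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Ground-truth record for a simulation
#'
#' @param planted_svs `data.frame` of planted SVs (may be empty).
#' @param cluster_classes Named character vector, feature to class.
#' @param true_pve Named numeric vector of variance fractions, sum <= 1.
#' @param causal_variants `data.frame(id, effect)` of causal variants.
#' @param seed Seed that produced the simulation.
#' @return A `sim_truth` list.
#' @export
sim_truth <- function(planted_svs = NULL, cluster_classes = NULL,
                      true_pve = NULL, causal_variants = NULL, seed = NA) {
  if (!is.null(true_pve)) {
    stopifnot(all(true_pve >= 0), sum(true_pve) <= 1 + 1e-12)
  }
  structure(list(planted_svs = planted_svs, cluster_classes = cluster_classes,
                 true_pve = true_pve, causal_variants = causal_variants,
                 seed = seed),
            class = "sim_truth")
}

#' Simulate a gene-cluster presence/absence matrix with known classes
#'
#' Draws features in the four occurrence classes used for pan-gene
#' analysis: core (present in every genome), softcore, dispensable and
#' private (single genome), with occupancy counts sampled uniformly
#' inside the class band of [gene_cluster_scheme()] for the given number
#' of genomes.
#'
#' @param n_genomes Number of genomes (columns), >= 2.
#' @param n_core,n_softcore,n_dispensable,n_private Feature counts per class.
#' @param seed Integer seed.
#' @return A list with `matrix` (a [presence_matrix()]) and `truth`
#'   (a [sim_truth()] whose `cluster_classes` maps feature to class).
#' @examples
#' sim <- simulate_pangene_matrix(32, 20, 5, 5, 3, seed = 7)
#' classify_gene_clusters(sim$matrix)$counts
#' @export
simulate_pangene_matrix <- function(n_genomes, n_core, n_softcore,
                                    n_dispensable, n_private, seed) {
  stopifnot(n_genomes >= 2, n_core >= 0, n_softcore >= 0,
            n_dispensable >= 0, n_private >= 0)
  scheme <- gene_cluster_scheme(n_genomes)
  counts <- c(core = n_core, softcore = n_softcore,
              dispensable = n_dispensable, private = n_private)
  for (cl in names(counts)) {
    band <- scheme$bands[[cl]]
    if (counts[[cl]] > 0 && (is.null(band) || band[1] > band[2]))
      stop_pansv("class band '%s' is empty for n_genomes = %d", cl, n_genomes)
  }
  with_seed(seed, {
    genomes <- paste0("G", seq_len(n_genomes))
    feats <- character(0); classes <- character(0); occ <- list()
    k <- 0L
    for (cl in names(counts)) {
      band <- scheme$bands[[cl]]
      for (i in seq_len(counts[[cl]])) {
        k <- k + 1L
        id <- sprintf("cluster_%04d", k)
        m <- if (band[1] == band[2]) band[1] else
          sample(seq(band[1], band[2]), 1)
        feats <- c(feats, id); classes <- c(classes, cl)
        occ[[id]] <- sample(genomes, m)
      }
    }
    mat <- matrix(0L, length(feats), n_genomes,
                  dimnames = list(feats, genomes))
    for (id in feats) mat[id, occ[[id]]] <- 1L
    list(matrix = presence_matrix(mat),
         truth = sim_truth(cluster_classes = stats::setNames(classes, feats),
                           seed = seed))
  })
}

#' Simulate a SNP + SV genotype panel with optional population structure
#'
#' Emits a homozygous-coded (`0`/`2`/`NA`) panel. Minor allele
#' frequencies are controlled exactly: for each variant the alternate
#' carrier count `k` is drawn uniformly over the counts whose frequency
#' `k/n` lies in `maf_range`, so the realized MAF is inside the
#' requested range by construction (before missingness injection). With
#' `n_subpops > 1`, carriers are allocated across equally sized
#' subpopulations with Dirichlet-weighted probabilities, which creates
#' allele-frequency divergence and hence non-trivial kinship structure.
#'
#' @param n_samples Number of samples.
#' @param n_snps,n_svs Number of SNP / SV columns.
#' @param maf_range Numeric pair in (0, 0.5].
#' @param missing_rate Per-entry missing probability in `[0, 1)`.
#' @param n_subpops Number of subpopulations (1 = panmictic).
#' @param seed Integer seed.
#' @param genome_length Span (bp) over which variant positions are drawn.
#' @param structure_alpha Dirichlet concentration for subpop carrier
#'   weights; smaller values give stronger divergence.
#' @return A [genotype_panel()] with an extra `subpop` element (integer
#'   subpopulation label per sample).
#' @export
simulate_genotype_matrix <- function(n_samples, n_snps, n_svs,
                                     maf_range = c(0.05, 0.5),
                                     missing_rate = 0, n_subpops = 1,
                                     seed, genome_length = 30e6,
                                     structure_alpha = 1) {
  stopifnot(n_samples >= 2, n_snps >= 0, n_svs >= 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], n_subpops >= 1)
  if (missing_rate >= 1 || missing_rate < 0)
    stop_pansv("missing_rate must be in [0, 1)")
  k_lo <- max(1L, as.integer(ceiling(maf_range[1] * n_samples)))
  k_hi <- as.integer(floor(maf_range[2] * n_samples))
  if (k_hi < k_lo)
    stop_pansv("maf_range [%g, %g] admits no carrier count for n = %d",
               maf_range[1], maf_range[2], n_samples)
  with_seed(seed, {
    samples <- paste0("S", seq_len(n_samples))
    subpop <- rep(seq_len(n_subpops), length.out = n_samples)
    n_var <- n_snps + n_svs
    class <- sample(c(rep("SNP", n_snps), rep("SV", n_svs)))
    pos <- sort(sample.int(genome_length, n_var))
    id <- character(n_var)
    id[class == "SNP"] <- paste0("snp_", seq_len(n_snps))
    id[class == "SV"] <- paste0("sv_", seq_len(n_svs))
    g <- matrix(0, n_samples, n_var, dimnames = list(samples, id))
    for (j in seq_len(n_var)) {
      k <- if (k_lo == k_hi) k_lo else
        sample(seq(k_lo, k_hi), 1)
      prob <- if (n_subpops == 1) NULL else {
        w <- stats::rgamma(n_subpops, shape = structure_alpha) + 1e-9
        (w / sum(w))[subpop]
      }
      carriers <- sample.int(n_samples, k, prob = prob)
      g[carriers, j] <- 2
    }
    if (missing_rate > 0) {
      miss <- stats::runif(length(g)) < missing_rate
      g[miss] <- NA
    }
    variants <- data.frame(id = id, chrom = "1", pos = pos, class = class,
                           stringsAsFactors = FALSE)
    panel <- genotype_panel(g, variants, samples)
    panel$subpop <- subpop
    panel
  })
}

#' Simulate a phenotype with target SNP and SV variance fractions
#'
#' Builds `y = intercept + g_snp + g_sv + e` where each polygenic term
#' is a linear combination of standardized causal dosages with normal
#' effects, rescaled so the realized sample variance of each term equals
#' its requested proportion of a unit total variance.
#'
#' @param panel A [genotype_panel()].
#' @param pve_snp,pve_sv Target variance fractions in `[0, 1]`,
#'   `pve_snp + pve_sv <= 1`.
#' @param n_causal_snp,n_causal_sv Number of causal variants per class
#'   (default: all of that class).
#' @param seed Integer seed.
#' @param intercept Population mean added to the phenotype.
#' @return List with `phenotype` (named numeric vector) and `truth`
#'   (a [sim_truth()] carrying `true_pve` and `causal_variants`).
#' @export
simulate_phenotype <- function(panel, pve_snp, pve_sv,
                               n_causal_snp = NULL, n_causal_sv = NULL,
                               seed, intercept = 0) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (pve_snp < 0 || pve_sv < 0)
    stop_pansv("variance fractions must be non-negative")
  if (pve_snp + pve_sv > 1)
    stop_pansv("pve_snp + pve_sv must be <= 1")
  is_snp <- panel$variants$class == "SNP"
  n_causal_snp <- n_causal_snp %||% sum(is_snp)
  n_causal_sv <- n_causal_sv %||% sum(!is_snp)
  stopifnot(n_causal_snp <= sum(is_snp), n_causal_sv <= sum(!is_snp))
  n <- nrow(panel$genotypes)
  with_seed(seed, {
    term <- function(idx, n_causal, pve) {
      if (pve == 0 || n_causal == 0)
        return(list(g = rep(0, n), causal = NULL))
      causal <- sample(which(idx), n_causal)
      W <- standardize_dosage(panel$genotypes[, causal, drop = FALSE])
      b <- stats::rnorm(n_causal)
      g <- drop(W %*% b)
      s <- stats::sd(g)
      if (s < 1e-12) stop_pansv("degenerate polygenic term (zero variance)")
      g <- g * sqrt(pve) / s
      list(g = g,
           causal = data.frame(id = panel$variants$id[causal],
                               effect = b * sqrt(pve) / s))
    }
    t1 <- term(is_snp, n_causal_snp, pve_snp)
    t2 <- term(!is_snp, n_causal_sv, pve_sv)
    pve_e <- 1 - pve_snp - pve_sv
    e <- stats::rnorm(n)
    if (pve_e > 0) e <- e * sqrt(pve_e) / stats::sd(e) else e <- rep(0, n)
    y <- intercept + t1$g + t2$g + e
    names(y) <- panel$sample_ids
    list(phenotype = y,
         truth = sim_truth(
           true_pve = c(snp = pve_snp, sv = pve_sv),
           causal_variants = rbind(t1$causal, t2$causal),
           seed = seed))
  })
}

# Column-standardize a dosage matrix: mean-impute missing entries, then
# scale each column to mean 0 / unit variance. Zero-variance columns are
# dropped with a warning by callers that cannot use them.
standardize_dosage <- function(g) {
  g <- as.matrix(g)
  for (j in seq_len(ncol(g))) {
    x <- g[, j]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    g[, j] <- x
  }
  mu <- colMeans(g)
  sd <- apply(g, 2, stats::sd)
  keep <- sd > 0
  sweep(sweep(g[, keep, drop = FALSE], 2, mu[keep]), 2, sd[keep], "/")
}
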