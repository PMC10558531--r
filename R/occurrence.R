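#' Feature-by-genome presence/absence matrix
#'
#' @param mat 0/1 matrix (features in rows, genomes in columns) with
#'   dimnames. Every feature must be present in at least one genome and
#'   identifiers must be unique.
#' @return A `presence_matrix` (the validated integer matrix).
#' @export
presence_matrix <- function(mat) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("feature_%04d", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("G", seq_len(ncol(mat)))
  if (nrow(mat) == 0 || ncol(mat) == 0) stop_pansv("empty presence matrix")
  if (!all(mat %in% c(0L, 1L))) stop_pansv("presence matrix must be 0/1")
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat)))
    stop_pansv("duplicate feature or genome identifiers")
  if (any(rowSums(mat) == 0))
    stop_pansv("every feature must be present in at least one genome")
  structure(mat, class = c("presence_matrix", class(mat)))
}

#' Occurrence classification scheme
#'
#' A named list of inclusive occupancy-count bands that must partition
#' `1..n_genomes` with no gaps or overlaps.
#'
#' @param bands Named list of integer pairs `c(lo, hi)`; empty bands
#'   (`lo > hi`) are allowed and match nothing.
#' @param n_genomes Total genome count the bands refer to.
#' @return An `occurrence_scheme` list with `bands` and `n_genomes`.
#' @export
occurrence_scheme <- function(bands, n_genomes) {
  covered <- unlist(lapply(bands, function(b)
    if (b[1] <= b[2]) seq(b[1], b[2]) else integer(0)))
  if (length(covered) != n_genomes || anyDuplicated(covered) ||
      !setequal(covered, seq_len(n_genomes)))
    stop_pansv("bands must partition 1..%d with no gaps or overlaps", n_genomes)
  structure(list(bands = bands, n_genomes = n_genomes),
            class = "occurrence_scheme")
}

#' Default gene-cluster occurrence bands
#'
#' For `n_genomes = 32` these are the standard pan-gene bands: core =
#' present in all 32 genomes, softcore = 26–31, dispensable = 2–25,
#' private = 1. For other genome counts the softcore band lower edge
#' generalizes to `ceiling(0.8125 * N)` (which reproduces 26 at N = 32).
#'
#' @param n_genomes Total genome count, >= 2.
#' @return An [occurrence_scheme()].
#' @export
gene_cluster_scheme <- function(n_genomes) {
  stopifnot(n_genomes >= 2)
  soft_lo <- as.integer(ceiling(0.8125 * n_genomes))
  occurrence_scheme(list(
    core = c(n_genomes, n_genomes),
    softcore = c(soft_lo, n_genomes - 1L),
    dispensable = c(2L, soft_lo - 1L),
    private = c(1L, 1L)
  ), n_genomes)
}

#' Default TE-family occurrence bands
#'
#' core = present in all genomes, rare = 1–5 genomes, variable = the
#' remainder (6–31 at N = 32).
#'
#' @param n_genomes Total genome count, >= 6 for these bands.
#' @return An [occurrence_scheme()].
#' @export
te_family_scheme <- function(n_genomes) {
  if (n_genomes < 6)
    stop_pansv("TE bands (rare = 1-5, variable = 6-%d) need n_genomes >= 6; pass a custom scheme",
               n_genomes - 1)
  occurrence_scheme(list(
    core = c(n_genomes, n_genomes),
    variable = c(6L, n_genomes - 1L),
    rare = c(1L, 5L)
  ), n_genomes)
}

classify_occurrence <- function(matrix, scheme) {
  stopifnot(inherits(matrix, "presence_matrix"),
            inherits(scheme, "occurrence_scheme"))
  if (ncol(matrix) != scheme$n_genomes)
    stop_pansv("scheme is for %d genomes but matrix has %d",
               scheme$n_genomes, ncol(matrix))
  occ <- rowSums(matrix)
  class <- rep(NA_character_, nrow(matrix))
  for (cl in names(scheme$bands)) {
    b <- scheme$bands[[cl]]
    class[occ >= b[1] & occ <= b[2]] <- cl
  }
  names(class) <- rownames(matrix)
  counts <- table(factor(class, levels = names(scheme$bands)))
  list(class = class, occupancy = stats::setNames(occ, rownames(matrix)),
       counts = counts,
       fractions = counts / length(class))
}

#' Classify gene clusters by occurrence across genomes
#'
#' Assigns each gene cluster to core / softcore / dispensable / private
#' based on the number of genomes it occurs in (presence of at least one
#' member per genome, not copy number).
#'
#' @param matrix A [presence_matrix()].
#' @param scheme An [occurrence_scheme()]; default [gene_cluster_scheme()]
#'   for the matrix's genome count.
#' @return List with `class` (named character vector), `occupancy`,
#'   `counts` and `fractions` per class.
#' @export
classify_gene_clusters <- function(matrix, scheme = NULL) {
  scheme <- scheme %||% gene_cluster_scheme(ncol(matrix))
  classify_occurrence(matrix, scheme)
}

#' Classify TE families by occurrence across genomes
#'
#' Classes are core (all genomes), variable and rare (1–5 genomes).
#'
#' @inheritParams classify_gene_clusters
#' @return As [classify_gene_clusters()], with classes
#'   core/variable/rare.
#' @export
classify_te_families <- function(matrix, scheme = NULL) {
  scheme <- scheme %||% te_family_scheme(ncol(matrix))
  classify_occurrence(matrix, scheme)
}

#' Pan/core saturation curves over random genome orderings
#'
#' For each subset size `k = 1..N` and each of `n_repeats` random genome
#' orderings, counts the pan size (features present in at least one of
#' the first `k` genomes) and the core size (features present in all
#' `k`). Summaries report the median and quartiles per `k`, the
#' statistics drawn in pan-genome saturation boxplots.
#'
#' @param matrix A [presence_matrix()].
#' @param n_repeats Number of random orderings (default 30).
#' @param seed Integer seed.
#' @return List with `samples` (`data.frame`: k, repeat_id, pan_size,
#'   core_size) and `summary` (`data.frame`: k, pan/core median and
#'   quartiles).
#' @export
pan_core_curve <- function(matrix, n_repeats = 30, seed = 1) {
  stopifnot(inherits(matrix, "presence_matrix"), n_repeats >= 1)
  n <- ncol(matrix)
  with_seed(seed, {
    recs <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      ord <- sample.int(n)
      cum_any <- rep(FALSE, nrow(matrix))
      cum_all <- rep(TRUE, nrow(matrix))
      pan <- integer(n); core <- integer(n)
      for (k in seq_len(n)) {
        col <- matrix[, ord[k]] > 0
        cum_any <- cum_any | col
        cum_all <- cum_all & col
        pan[k] <- sum(cum_any)
        core[k] <- sum(cum_all)
      }
      recs[[r]] <- data.frame(k = seq_len(n), repeat_id = r,
                              pan_size = pan, core_size = core)
    }
    samples <- do.call(rbind, recs)
    q <- function(x, p) as.numeric(stats::quantile(x, p))
    summary <- do.call(rbind, lapply(split(samples, samples$k), function(d)
      data.frame(k = d$k[1],
                 pan_q1 = q(d$pan_size, 0.25), pan_median = q(d$pan_size, 0.5),
                 pan_q3 = q(d$pan_size, 0.75),
                 core_q1 = q(d$core_size, 0.25),
                 core_median = q(d$core_size, 0.5),
                 core_q3 = q(d$core_size, 0.75))))
    rownames(summary) <- NULL
    list(samples = samples, summary = summary)
  })
}

#' LTR insertion time from LTR-pair divergence
#'
#' The two long terminal repeats of a retrotransposon are identical at
#' insertion and diverge at the neutral mutation rate afterwards, so an
#' element with per-site divergence `K` inserted `T = K / (2 * mu_rate)`
#' years ago.
#'
#' @param K Divergence between the two LTRs (substitutions per site).
#' @param mu_rate Mutation rate in substitutions per site per year
#'   (default `7e-9`, the rate used for *A. thaliana* TE dating).
#' @return Insertion time(s) in years.
#' @examples
#' ltr_insertion_time(0.014)  # 1e6 years
#' @export
ltr_insertion_time <- function(K, mu_rate = 7e-9) {
  if (any(K < 0)) stop_pansv("LTR divergence K must be >= 0")
  if (any(mu_rate <= 0)) stop_pansv("mu_rate must be > 0")
  K / (2 * mu_rate)
}

#' Read / write a presence matrix as TSV
#'
#' Plain features-by-genomes 0/1 table with a header row of genome
#' identifiers and feature identifiers in the first column.
#'
#' @param path File path.
#' @param matrix A [presence_matrix()] (for writing).
#' @return `read_presence_matrix` returns a [presence_matrix()].
#' @export
read_presence_matrix <- function(path) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  presence_matrix(as.matrix(d))
}

#' @rdname read_presence_matrix
#' @export
write_presence_matrix <- function(matrix, path) {
  d <- data.frame(feature = rownames(matrix), unclass(matrix),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
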