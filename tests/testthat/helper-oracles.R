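# Independent oracles used to cross-check the package's algorithms.
# These deliberately re-derive results by different routes (pair
# enumeration, direct linear algebra, string substitution) and must not
# call the code paths they check.

# Brute-force bubble enumerator: consider every ordered pair of
# reference-backbone segments that ALL walks traverse; it is a candidate
# bubble if at least two distinct sequences are spelled between the two
# anchors across walks. Report candidates that contain no smaller
# candidate (minimal anchor pairs).
brute_force_bubbles <- function(graph) {
  ref <- graph$walks[[graph$reference_walk]]
  out <- list()
  for (ch in names(ref)) {
    ref_ids <- ref[[ch]]
    n <- length(ref_ids)
    walks <- lapply(graph$walks, `[[`, ch)
    spell_pair <- function(w, a, b) {
      i <- match(a, w); j <- match(b, w)
      if (is.na(i) || is.na(j) || j < i) return(NA_character_)
      if (j == i + 1) return("")
      paste(graph$segments[w[(i + 1):(j - 1)]], collapse = "")
    }
    cand <- list()
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      spells <- vapply(walks, spell_pair, character(1),
                       a = ref_ids[i], b = ref_ids[j])
      if (anyNA(spells)) next             # some walk skips an anchor
      if (length(unique(spells)) >= 2)
        cand[[length(cand) + 1L]] <- c(i, j)
    }
    if (length(cand) == 0) next
    cm <- do.call(rbind, cand)
    minimal <- vapply(seq_len(nrow(cm)), function(k) {
      inside <- cm[, 1] >= cm[k, 1] & cm[, 2] <= cm[k, 2] &
        !(cm[, 1] == cm[k, 1] & cm[, 2] == cm[k, 2])
      !any(inside)
    }, logical(1))
    cm <- cm[minimal, , drop = FALSE]
    cm <- cm[order(cm[, 1]), , drop = FALSE]
    for (k in seq_len(nrow(cm))) {
      spells <- vapply(walks, spell_pair, character(1),
                       a = ref_ids[cm[k, 1]], b = ref_ids[cm[k, 2]])
      out[[length(out) + 1L]] <- list(
        chrom = ch, source = ref_ids[cm[k, 1]], sink = ref_ids[cm[k, 2]],
        alleles = sort(unique(unname(spells))))
    }
  }
  out
}

# Random small reference-backbone graph built from a random variant
# table; cross-sample interval overlap is allowed (exercises bubble
# merging), within-sample overlap is not (rejected and redrawn).
random_test_graph <- function(seed, max_segments = 30) {
  set.seed(seed)
  repeat {
    ref_len <- sample(40:80, 1)
    ref <- paste(sample(c("A", "C", "G", "T"), ref_len, replace = TRUE),
                 collapse = "")
    n_samples <- sample(2:4, 1)
    rows <- list()
    for (s in paste0("S", seq_len(n_samples))) {
      n_v <- sample(0:3, 1)
      taken <- matrix(numeric(0), 0, 2)
      for (v in seq_len(n_v)) {
        for (try in 1:20) {
          rl <- sample(0:6, 1)              # 0 = insertion
          start <- sample(2:(ref_len - rl - 1), 1)
          s0 <- start - 1; e0 <- s0 + rl
          if (nrow(taken) && any(s0 <= taken[, 2] & e0 >= taken[, 1])) next
          ref_al <- if (rl == 0) "" else substr(ref, start, start + rl - 1)
          al <- sample(0:6, 1)
          alt_al <- if (al == 0) "" else
            paste(sample(c("A", "C", "G", "T"), al, replace = TRUE),
                  collapse = "")
          if (alt_al == ref_al) next
          taken <- rbind(taken, c(s0, e0))
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = "c1", start = start, ref_allele = ref_al,
            alt_allele = alt_al, sample = s, stringsAsFactors = FALSE)
          break
        }
      }
    }
    variants <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(0), start = integer(0),
                 ref_allele = character(0), alt_allele = character(0),
                 sample = character(0))
    g <- build_graph(c(c1 = ref), variants,
                     samples = paste0("S", seq_len(n_samples)))
    if (length(g$segments) <= max_segments) return(g)
  }
}

# Apply a sample's variant rows to the reference by direct string
# surgery (right to left), independent of the graph machinery.
apply_variants_string <- function(ref, rows) {
  rows <- rows[order(rows$start, decreasing = TRUE), , drop = FALSE]
  out <- ref
  for (i in seq_len(nrow(rows))) {
    s <- rows$start[i]
    rl <- nchar(rows$ref_allele[i])
    out <- paste0(substr(out, 1, s - 1), rows$alt_allele[i],
                  substr(out, s + rl, nchar(out)))
  }
  out
}

# Restricted log-likelihood evaluated from first principles with
# determinant() and solve() — no Cholesky/eigen shortcuts shared with
# the fitting code.
rll_direct <- function(y, G, s2g, s2e) {
  n <- length(y)
  V <- s2g * unclass(G) + diag(s2e, n)
  X <- matrix(1, n, 1)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  mu <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% mu
  -0.5 * (as.numeric(determinant(V, logarithm = TRUE)$modulus) +
            log(XtViX[1, 1]) + t(r) %*% Vi %*% r)[1, 1]
}

# Grid-search REML: maximize rll_direct over a (pve, total-variance)
# grid; returns the best grid point.
grid_reml <- function(y, G, pve_grid = seq(0, 0.99, by = 0.01),
                      scale_grid = NULL) {
  vy <- var(y)
  scale_grid <- scale_grid %||% vy * seq(0.5, 1.6, by = 0.02)
  best <- c(ll = -Inf, pve = NA, s2g = NA, s2e = NA)
  for (tot in scale_grid) for (h in pve_grid) {
    ll <- rll_direct(y, G, h * tot, (1 - h) * tot)
    if (ll > best[["ll"]])
      best <- c(ll = ll, pve = h, s2g = h * tot, s2e = (1 - h) * tot)
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a
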