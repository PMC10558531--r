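#' Evaluate an expression under a local random seed
#'
#' Saves and restores `.Random.seed` so simulation functions are
#' deterministic for a given `seed` without disturbing the caller's
#' random-number stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA string(s)
#' @param n Number of strings.
#' @param len Length (recycled).
#' @return Character vector of A/C/G/T strings.
#' @keywords internal
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l) {
    if (l == 0L) "" else paste(sample(DNA_BASES, l, replace = TRUE), collapse = "")
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pansv <- function(...) stop(sprintf(...), call. = FALSE)
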