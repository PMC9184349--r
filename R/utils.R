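## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards so seeded calls do not perturb the session stream.
#' A `NULL` seed evaluates `code` against the current stream.
#'
#' @param seed integer scalar or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic child seed for unit k of a seeded loop; kept < 2^31 - 1.
subSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 2147483647L + 104729L * as.integer(k)) %% 2147483647L
}

## Row-wise minima; max.col is C-level so this beats apply(m, 1, min).
rowMins <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

## All unordered sample pairs in canonical (k < l) order.
pairIndices <- function(n) {
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  t(combn(n, 2L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
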