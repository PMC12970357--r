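#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the session RNG, evaluates `expr`, and restores the previous RNG
#' state afterwards, so package functions are deterministic under their
#' `seed` argument without clobbering the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from a parent seed, kept below 2^31.
# Used wherever one user-facing seed must drive several independent
# sub-procedures (bootstrap replicates, repeats, folds).
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# min-max scale a numeric vector to [0, 1]; constant input maps to 0
minmax01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (r[2] <= r[1]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

stopifnot_finite_matrix <- function(X, what = "feature matrix") {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!all(is.finite(X))) stop(what, " contains non-finite values")
  X
}
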