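#' @keywords internal
"_PACKAGE"

#' @useDynLib ikbrnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rlnorm rgamma pt cor sd setNames
#' @importFrom utils head tail
NULL

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# All module-level randomness is funneled through this so that a single integer
# seed fully determines each operation's output without clobbering the session.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# round-half-up (R's round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# scatter-add rows of `x` (m x d) into an n x d matrix by integer index `idx`.
scatter_add <- function(x, idx, n) {
  x <- as.matrix(x)
  out <- matrix(0, n, ncol(x))
  s <- rowsum(x, group = idx, reorder = FALSE)
  out[as.integer(rownames(s)), ] <- s
  out
}

# segment sum of a vector by integer group index, returning length-n vector
segment_sum <- function(v, idx, n) {
  out <- numeric(n)
  s <- rowsum(matrix(v, ncol = 1), group = idx, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
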