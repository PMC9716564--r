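#' Logistic sigmoid
#'
#' @param x numeric array.
#' @return `1 / (1 + exp(-x))`, same shape as `x`.
#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Softmax over a vector
#'
#' Numerically stabilised (max subtracted before exponentiation).
#'
#' @param z numeric vector of unnormalised scores.
#' @return probability vector of the same length summing to 1.
#' @export
softmax <- function(z) {
  z <- as.numeric(z)
  e <- exp(z - max(z))
  e / sum(e)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the ambient RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Wrap an angle in degrees to [0, 360).
wrap_theta <- function(theta) theta %% 360

stopf <- function(...) stop(sprintf(...), call. = FALSE)
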