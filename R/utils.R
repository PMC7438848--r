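#' @useDynLib epidisc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

#' Derive per-stage seeds from one master seed
#'
#' Fans a single master seed out into reproducible sub-seeds (one per named
#' stage) via a Lehmer multiplicative congruential step, so pipeline stages
#' can be re-run independently with the same randomness.
#'
#' @param seed Master seed (integer).
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
deriveSeeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  m <- 2147483647  # 2^31 - 1 (prime)
  s <- (abs(as.numeric(seed)) %% (m - 1)) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% m
    out[i] <- s
  }
  as.integer(out)
}

stopIfNotFinite <- function(x, what = "input") {
  if (!length(x)) stop(what, " is empty")
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}
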