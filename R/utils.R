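#' @keywords internal
"_PACKAGE"

#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library calls never perturb a caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
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

#' Derive a per-item seed from a master seed
#'
#' Deterministic integer mixing so that each sample's stream depends only on
#' `(master_seed, index, label)` and never on generation order. The result is
#' kept in `[0, 2^31 - 1)` so it is always a valid R seed.
#'
#' @param master_seed integer master seed.
#' @param index 1-based item index.
#' @param salt extra integer component (e.g. a label code).
#' @return a non-negative integer seed.
#' @export
derive_seed <- function(master_seed, index, salt = 0L) {
  # 64-bit-free LCG-style mixing in double precision: all intermediates
  # stay below 2^52 so the arithmetic is exact.
  m <- 2147483647  # 2^31 - 1 (Mersenne prime)
  h <- (as.numeric(master_seed) %% m + 1) * 48271 %% m
  h <- (h + as.numeric(index) * 16807) %% m
  h <- (h * 69621 + as.numeric(salt) * 40692 + 12345) %% m
  as.integer(h)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("non-finite values in %s", what)
  invisible(x)
}
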