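#' Round half away from zero
#'
#' All split and flip-count sizes in the package use round-half-up
#' (`floor(x + 0.5)`) rather than R's banker's rounding, so that e.g.
#' 15% of 10 tiles is 2 flips, not 1.
#'
#' @param x Numeric vector (assumed non-negative).
#' @return Integer vector.
#' @export
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

# Largest usable seed: R's set.seed() takes a 32-bit integer.
.SEED_MOD <- 2147483647L

#' Derive a reproducible child seed
#'
#' A single experiment seed fans out into per-repeat and per-member seeds
#' via a fixed integer hash, so any stage of a run can be replayed in
#' isolation. `derive_seed(seed, i)` gives the seed for stream `i`
#' (e.g. repeat index); `derive_seed(seed, i, j)` for sub-stream `j`
#' (e.g. member j of repeat i).
#'
#' @param seed Non-negative integer master seed.
#' @param i,j Non-negative integer stream indices.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, i, j = 0L) {
  stopifnot(is.numeric(seed), seed >= 0, i >= 0, j >= 0)
  # double precision is exact far beyond these magnitudes
  v <- (seed %% .SEED_MOD) * 1e4 + (i %% 1e4)
  v <- (v %% .SEED_MOD) * 131 + (j %% 131)
  as.integer(v %% .SEED_MOD)
}

#' Evaluate an expression under a local RNG seed
#'
#' Wrapper around [withr::with_seed()]: the global RNG state is untouched.
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed %% .SEED_MOD), expr)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

abort_bad <- function(...) stop(paste0(...), call. = FALSE)

# clamp to [0, 1] preserving dim and other attributes
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
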