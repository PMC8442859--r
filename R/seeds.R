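#' Derive a reproducible substream seed
#'
#' All stochastic stages in the package draw their randomness from a single
#' master seed expanded into named substreams, so that adding a stage (or
#' re-ordering stages) never perturbs the random numbers used by another.
#' The derivation hashes the stage key into a 31-bit integer with a
#' Horner-scheme polynomial over the key's UTF-8 bytes and mixes in the
#' master seed; it is pure arithmetic, documented here, and stable across
#' platforms and package versions.
#'
#' @param seed Integer master seed.
#' @param key Character scalar naming the stage/substream (e.g. "founders").
#' @return An integer in [0, 2^31 - 2] suitable for [set.seed()].
#' @examples
#' substream_seed(1, "founders")
#' substream_seed(1, "breeding") # different stream, same master seed
#' @export
substream_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(key), length(key) == 1L)
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(key)) {
    h <- (h * 131 + b) %% m
  }
  # one multiplicative mixing step (Lehmer / MINSTD multiplier)
  as.integer((h * 48271) %% m)
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
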