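# Internal helpers: reproducible sub-stream seeding and local RNG scopes.

# Derive a 31-bit seed from a master seed and a stream label, so that every
# stochastic operation is individually replayable without consuming the
# caller's RNG state.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
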