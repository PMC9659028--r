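#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` (Mersenne-Twister,
#' Rejection sampling) and restores the caller's RNG state afterwards, so
#' package functions are pure functions of their seed arguments and never
#' perturb user randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

#' Derive a child seed from a base seed and stream indices
#'
#' Mixes integer indices into a base seed with a fixed LCG-style hash so
#' per-slide / per-epoch streams are distinct, reproducible, and stay within
#' 32-bit integer range.
#'
#' @param seed Base integer seed.
#' @param ... Further non-negative integer indices.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1
  s <- as.double(seed %% m)
  for (k in c(...)) {
    s <- (s * 69069 + as.double(k) + 12345) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

# sample() without the length-1 surprise
sample_exact <- function(x, size) {
  x[sample.int(length(x), size)]
}
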