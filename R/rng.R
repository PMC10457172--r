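#' Derive a child random seed from a master seed
#'
#' Every generator in the package draws its randomness from a child stream
#' derived from one master seed by a fixed per-generator offset, so that a
#' single integer reproduces the full synthetic data set byte for byte while
#' keeping the streams of different generators independent of the order in
#' which they are called.
#'
#' @param seed master seed (single integer).
#' @param stream fixed integer offset identifying the consumer.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 31)
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.numeric(stream), length(stream) == 1)
  m <- 2147483647  # 2^31 - 1, Mersenne prime modulus
  s <- (abs(seed) %% m)
  # two rounds of a multiplicative congruential mix keep streams decorrelated
  s <- (s * 48271 + stream * 7919 + 1) %% m
  s <- (s * 16807 + 12345) %% m
  as.integer(s %% (m - 2) + 1)
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
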