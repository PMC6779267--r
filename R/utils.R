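# Internal helpers shared across modules.

# Seed the R RNG with a plain integer seed.
seed_rng <- function(seed) set.seed(as.integer(seed))

#' Derive a sub-seed from a master seed
#'
#' Counter-based derivation used everywhere a pipeline needs several
#' independent streams (per grid cell, per lesion target, per repetition):
#' deterministic in `(seed, index)`, stays below 2^31, and distinct indices
#' give distinct sub-seeds for any fixed master seed.
#'
#' @param seed Master integer seed.
#' @param index Nonnegative integer counter.
#' @return An integer sub-seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 1299709
  as.integer(s %% 2147483647)
}

upper_vals <- function(m) m[upper.tri(m)]
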