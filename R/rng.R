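# Counter-based Gaussian draws.
#
# Every random number used by the synthetic-model builders is addressed by a
# structural key (seed, stream id, chain, class id, position, ...) rather than
# drawn from a sequential stream.  Adding modes to a model therefore never
# perturbs the numbers assigned to earlier modes, and a draw is reproducible
# from its key alone.  The key is mixed down to a 31-bit integer which seeds
# R's Mersenne-Twister; the first N(0,1) variate of that stream is the draw.

# exact 32-bit modular product using doubles (operands < 2^32)
.mulmod32 <- function(a, b) {
  a0 <- a %% 65536
  a1 <- (a - a0) / 65536
  (((a1 * b) %% 65536) * 65536 + a0 * b) %% 4294967296
}

# mix an integer key vector into [0, 2^31 - 2]
.mix_key <- function(seed, keys) {
  h <- (seed %% 4294967296)
  h <- .mulmod32(h + 2654435769, 2246822519)
  for (k in keys) {
    h <- (h + (k %% 4294967296) + 1) %% 4294967296
    h <- .mulmod32(h, 2654435761)
    h <- (h + (h - h %% 65536) / 65536) %% 4294967296
  }
  h %% 2147483646
}

# one standard-normal draw addressed by (seed, keys); caller is responsible
# for preserving the global RNG state (see .with_preserved_rng)
.counter_rnorm <- function(seed, keys) {
  set.seed(.mix_key(seed, keys))
  stats::rnorm(1L)
}

# evaluate expr while protecting the caller's .Random.seed
.with_preserved_rng <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  expr
}
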