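# Evaluate expr under a fixed Mersenne-Twister state without disturbing the
# caller's RNG stream; all seeded package entry points funnel through this so
# results are bit-reproducible across platforms.
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# derive a stream-specific child seed, kept inside 32-bit integer range
.childSeed <- function(seed, k) {
  (as.double(seed) * 7919 + k * 104729) %% 2147483647
}
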