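# Evaluate code under a temporary RNG state; the caller's stream is
# untouched. NULL seed runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# counter-based per-stage seed derivation from one global seed; keeps the
# result a valid 32-bit integer
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 7919 + counter * 104729) %% 2147483647)
}
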