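# Internal helpers.

# Evaluate expr with a local RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic child seed for stage `i` of a run seeded with `seed`;
# kept within the 32-bit integer range.
child_seed <- function(seed, i) {
  (as.numeric(seed) * 1009 + 97 * i) %% 2147483647
}
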