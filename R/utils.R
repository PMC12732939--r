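# Run expr with a temporary RNG seed, restoring the caller's stream after.
# Keeps every stochastic routine reproducible from its own `seed` argument
# without clobbering the session RNG.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Nearest-integer rounding, halves away from zero (round() rounds halves to
# even, which would turn 2/3 of 72 into the wrong partition size).
round_half_up <- function(x) floor(x + 0.5)
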