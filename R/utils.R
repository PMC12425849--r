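# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is untouched. A NULL seed uses (and advances) the
# global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

# One master seed deterministically spawns `n` independent sub-seeds, so
# per-participant permutation streams do not depend on how many random
# draws any other participant consumed.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
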