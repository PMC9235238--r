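# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so library calls never perturb user randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying inside the
# 32-bit signed-integer range R requires.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 9973) %% 2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
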