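# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. All seeded entry points funnel through this so that
# package randomness never perturbs (or depends on) the session RNG.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed from a base seed and a stream index, kept within
# 32-bit integer range
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
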