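# Small internal utilities.

# Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb the global stream.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Deterministic 32-bit sub-seed derived from a master seed and a label, so
# each generator has its own reproducible stream.
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
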