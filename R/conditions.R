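# Classed conditions so the CLI can map failures to exit codes:
# sip_validation_error -> 2 (bad input), sip_undefined_error -> 3
# (a statistic is mathematically undefined for this input, e.g. a bottle
# with no heavy fractions).

sip_stop <- function(msg, class = "sip_validation_error") {
  stop(structure(
    class = c(class, "sipError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

sip_undefined <- function(msg) sip_stop(msg, class = "sip_undefined_error")

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so seeded helpers do not clobber user state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    sip_stop("`seed` must be a single number")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}
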