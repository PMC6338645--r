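# Seeded-RNG helpers: every stochastic function takes an integer seed and
# leaves the global RNG state untouched.

with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic sub-stream seed for the k-th internal draw of a generator
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * k) %% (.Machine$integer.max - 1)) + 1L
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

clamp01 <- function(x) pmin(1, pmax(0, x))
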