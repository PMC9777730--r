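# internal helpers shared across modules

# run `expr` under a temporary RNG state seeded with `seed`; restores (or
# removes) .Random.seed afterwards so simulation never perturbs the caller's
# stream
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# splittable child seed: deterministic in (seed, index), stays below 2^31
child_seed <- function(seed, index) {
  as.integer(((seed %% 2147483647) * 48271 + index * 7919) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
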