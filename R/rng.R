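# Seeded RNG helpers. Every stochastic operation in the package takes an
# explicit seed and runs under it without disturbing the caller's global
# RNG state.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Minimal closure-based RNG view used where a function draws repeatedly.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- with_seed(seed, {
    runif(1)  # advance once so the state is seed-derived
    get(".Random.seed", envir = globalenv())
  })
  run <- function(fn) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", envir = globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    fn()
  }
  list(
    sample = function(n, ...) run(function() sample(n, ...)),
    runif = function(n, ...) run(function() runif(n, ...)),
    rnorm = function(n, ...) run(function() rnorm(n, ...)),
    run = run
  )
}
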