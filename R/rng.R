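# Seeded random-number streams that leave the caller's RNG state untouched.
# Every stochastic operation in the package draws from one of these, so runs
# are reproducible from their recorded seeds alone.

local_rng <- function(seed) {
  state <- NULL
  with_state <- function(expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = globalenv())
    res <- expr
    state <<- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
    res
  }
  list(
    runif = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    rpois = function(n, lambda) with_state(stats::rpois(n, lambda)),
    rgamma = function(n, shape, rate = 1) with_state(stats::rgamma(n, shape, rate = rate)),
    rlnorm = function(n, meanlog, sdlog) with_state(stats::rlnorm(n, meanlog, sdlog)),
    sample_int = function(n, size, replace = FALSE, prob = NULL)
      with_state(sample.int(n, size, replace = replace, prob = prob)),
    rdirichlet = function(alpha) {
      g <- with_state(stats::rgamma(length(alpha), alpha, rate = 1))
      g / sum(g)
    })
}

# derive a child seed (kept below 2^31 so it is a valid R integer seed)
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1103 + i * 7919) %% 2147483647)
}
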