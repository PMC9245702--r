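# Independent oracles and shared fixtures for the test suite.

# Inverse-CDF sampler for a truncated discrete power law P(x) propto x^(-a)
# on {x_min, ..., x_max}; independent of the package's MLE fitting path.
rdiscrete_powerlaw <- function(n, a, x_min = 1, x_max = 1000) {
  ks <- x_min:x_max
  p <- ks^(-a)
  sample(ks, n, replace = TRUE, prob = p / sum(p))
}

# Expensive shared fixtures, computed once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# critical-growth-factor estimate at lambda = 0.4 (shared by the
# self-organization and heterogeneity tests)
gc_lambda04 <- function() {
  fixture("gc04", estimate_gc(lambda = 0.4, P = 200, t_max = 1e4,
                              n_rep = 20, tol = 0.01, seed = 71))
}

# near-critical single-species pattern statistics at lambda = 0.89 (shared
# by the two directed-percolation exponent tests)
critical_pattern_run <- function() {
  fixture("dp_run",
          critical_pattern_statistics(lambda = 0.89, P = 1000L, t_max = 5e4,
                                      burn_in = 1e4, seed = 20260921))
}
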