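test_that("coexistence fixed point matches the closed form and its monotonicity", {
  expect_equal(equilibrium_abundance(10, 0, 100), 10)
  expect_equal(equilibrium_abundance(10, 0.1, 1), 10)
  expect_equal(equilibrium_abundance(10, 0.1, 5), 10 / 1.4)
  # strictly decreasing in S for alpha > 0, constant for alpha = 0
  S <- 1:50
  ns <- equilibrium_abundance(10, 0.1, S)
  expect_true(all(diff(ns) < 0))
  expect_equal(equilibrium_abundance(10, 0, S), rep(10, 50))
  expect_error(equilibrium_abundance(-1, 0.1, 5), "K")
})

test_that("effective growth factor matches hand-computed cases", {
  p <- model_params(K = 10, alpha = 0.1, S = 2, P = 3)
  f <- rbind(c(0, 0), c(5, 10), c(7, 0))
  g <- effective_growth_factor(f, p)
  expect_equal(g[1, ], c(1, 1))        # no competitors anywhere on patch 1
  expect_equal(g[2, 1], 1 - 0.1 * 10 / 10) # competitor at N = 10 -> 0.9
  expect_equal(g[2, 2], 1 - 0.1 * 5 / 10)
  expect_equal(g[3, 2], 1 - 0.1 * 7 / 10)
  expect_equal(g[3, 1], 1)             # species 2 absent from patch 3
  expect_true(all(g <= 1))
})

test_that("heterogeneous growth factor reduces to the homogeneous one", {
  p <- model_params(S = 4, P = 6)
  set.seed(3)
  f <- matrix(rpois(24, 5), 6, 4)
  A <- matrix(p$alpha, 4, 4)
  het <- heterogeneous_params(rep(p$r, 4), rep(p$lambda, 4), A)
  expect_equal(effective_growth_factor(f, p, het),
               effective_growth_factor(f, p))
})

test_that("the two groupings of the growth term agree on random fields", {
  set.seed(11)
  for (topo in c("nearest_neighbor_1d", "global")) {
    p <- model_params(S = 5, P = 12, topology = topo, lambda = 0.3)
    f <- matrix(rpois(60, 8), 12, 5)
    expect_equal(deterministic_rates(f, p, grouping = "growth_factor"),
                 deterministic_rates(f, p, grouping = "logistic"),
                 tolerance = 1e-12)
    het <- draw_heterogeneous_params(p, 0.03, 0.5 / p$S, 0.03)
    expect_equal(deterministic_rates(f, p, het, grouping = "growth_factor"),
                 deterministic_rates(f, p, het, grouping = "logistic"),
                 tolerance = 1e-12)
  }
})

test_that("the coexistence fixed point has zero deterministic rate", {
  for (topo in c("nearest_neighbor_1d", "global")) {
    p <- model_params(S = 5, P = 10, topology = topo)
    nstar <- equilibrium_abundance(p$K, p$alpha, p$S)
    f <- matrix(nstar, 10, 5)
    expect_equal(max(abs(deterministic_rates(f, p))), 0, tolerance = 1e-12)
    # the empty metacommunity is a fixed point too
    expect_equal(max(abs(deterministic_rates(f * 0, p))), 0)
  }
})

test_that("dispersal moves individuals but conserves each species' total", {
  set.seed(4)
  for (topo in c("nearest_neighbor_1d", "global")) {
    p <- model_params(S = 3, P = 20, lambda = 0.7, topology = topo)
    f <- matrix(rpois(60, 6), 20, 3)
    d <- metacrit:::dispersal_term(f, p)
    expect_equal(colSums(d), rep(0, 3), tolerance = 1e-12)
    # r = 0 leaves only dispersal
    p0 <- p; p0$r <- 0
    expect_equal(colSums(deterministic_rates(f, p0)), rep(0, 3),
                 tolerance = 1e-12)
  }
  # nearest-neighbour stencil against a hand computation with wraparound
  p <- model_params(S = 1, P = 4, lambda = 1)
  f <- cbind(c(4, 0, 2, 6))
  d <- metacrit:::dispersal_term(f, p)
  expect_equal(as.vector(d), 0.5 * c(0 + 6 - 8, 4 + 2 - 0, 0 + 6 - 4, 2 + 4 - 12))
})

test_that("field observables are mutually consistent", {
  p <- model_params(S = 3, P = 5)
  set.seed(8)
  f <- matrix(rpois(15, 4), 5, 3)
  obs <- field_observables(f, p)
  sp <- species_observables(f, p)
  expect_equal(obs$mean_abundance, mean(sp$species_mean))
  expect_equal(obs$mean_geff, mean(sp$geff_species))
  expect_equal(obs$n_extant_species, sum(!sp$extinct))
  expect_error(field_observables(matrix(1, 2, 2), p), "5 x 3")
})
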