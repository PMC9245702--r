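test_that("the all-extinct state is absorbing", {
  p <- model_params(S = 3, P = 10, lambda = 0.5)
  zero <- matrix(0, 10, 3)
  sim <- simulate_metacommunity(p, t_max = 50, init = zero, seed = 1)
  expect_equal(sum(abs(sim$final_field)), 0)
  expect_true(all(sim$summary$mean_abundance == 0))
})

test_that("a species stays extinct once its total abundance is zero", {
  p <- model_params(S = 2, P = 20, lambda = 0.3)
  init <- cbind(rpois(20, 8), 0) # species 2 starts globally extinct
  sim <- simulate_metacommunity(p, t_max = 200, init = init, seed = 2,
                                record_species = TRUE)
  expect_equal(max(sim$species_mean[, 2]), 0)
})

test_that("one stochastic generation has the Euler drift as mean and Poisson variance", {
  # single patch, single species, no dispersal or competition: the
  # one-generation deterministic map phi(N) composed of Euler substeps gives
  # the Poisson mean, so sample mean -> phi(N) and sample variance -> phi(N)
  p <- model_params(r = 0.3, K = 10, alpha = 0, lambda = 0, S = 1, P = 1)
  N0 <- 4
  det <- simulate_metacommunity(p, t_max = 1, init = matrix(N0, 1, 1),
                                noise = FALSE)
  phi <- as.numeric(det$final_field)
  expect_gt(phi, N0) # logistic growth below K
  set.seed(5)
  draws <- replicate(4000, {
    as.numeric(simulate_metacommunity(p, t_max = 1,
                                      init = matrix(N0, 1, 1))$final_field)
  })
  se_mean <- sqrt(phi) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - phi), 4 * se_mean)
  # Poisson: variance equals the mean; sd of the sample variance ~ sqrt(2/n)*var
  expect_lt(abs(var(draws) - phi), 5 * sqrt(2 / length(draws)) * phi + 0.1)
})

test_that("noise-free dynamics are stationary at the coexistence fixed point", {
  for (topo in c("nearest_neighbor_1d", "global")) {
    p <- model_params(S = 4, P = 15, lambda = 0.6, topology = topo)
    nstar <- equilibrium_abundance(p$K, p$alpha, p$S)
    init <- matrix(nstar, 15, 4)
    sim <- simulate_metacommunity(p, t_max = 50, init = init, noise = FALSE)
    expect_equal(max(abs(sim$final_field - nstar)), 0, tolerance = 1e-9)
  }
})

test_that("with r = 0 and noise off the dispersal operator conserves totals", {
  for (topo in c("nearest_neighbor_1d", "global")) {
    p <- model_params(S = 2, P = 12, lambda = 0.8, topology = topo)
    p$r <- 0
    set.seed(6)
    init <- matrix(rpois(24, 7), 12, 2)
    sim <- simulate_metacommunity(p, t_max = 100, init = init, noise = FALSE)
    expect_equal(colSums(sim$final_field), colSums(init), tolerance = 1e-8)
    # and the profile flattens toward the per-species mean
    expect_lt(max(abs(sweep(sim$final_field, 2, colMeans(init)))), 1)
  }
})

test_that("runs with the same seed are identical, different seeds differ", {
  p <- model_params(S = 3, P = 30, lambda = 0.4)
  s1 <- simulate_metacommunity(p, t_max = 100, seed = 9, record_species = TRUE)
  s2 <- simulate_metacommunity(p, t_max = 100, seed = 9, record_species = TRUE)
  expect_identical(s1$final_field, s2$final_field)
  expect_identical(s1$summary, s2$summary)
  s3 <- simulate_metacommunity(p, t_max = 100, seed = 10)
  expect_false(identical(s1$final_field, s3$final_field))
})

test_that("the standard initial condition is Poisson around K", {
  p <- model_params(K = 10, S = 4, P = 300)
  set.seed(12)
  f <- initial_condition(p)
  expect_true(all(f == round(f)) && all(f >= 0))
  se <- sqrt(p$K / length(f))
  expect_lt(abs(mean(f) - p$K), 4 * se)
  p0 <- p; p0$K <- 1e-12
  expect_equal(sum(initial_condition(p0)), 0) # K -> 0 gives the empty field
  set.seed(33); a <- initial_condition(p)
  set.seed(33); b <- initial_condition(p)
  expect_identical(a, b)
})

test_that("occupancy matrices reflect presence and absence", {
  p <- model_params(S = 2, P = 8, lambda = 0.2, K = 10)
  zero <- matrix(0, 8, 2)
  sim0 <- simulate_metacommunity(p, t_max = 20, init = zero, seed = 3,
                                 occupancy_species = 1:2)
  expect_false(any(occupancy(sim0, 1)))
  expect_false(any(occupancy(sim0, 2)))
  # a comfortably supercritical single species stays present everywhere
  sim1 <- simulate_single_species(g = 1, lambda = 0.5, P = 30, K = 50,
                                  t_max = 30, seed = 4)
  expect_true(all(occupancy(sim1)))
  expect_error(occupancy(sim0, 5), "not recorded")
})

test_that("without dispersal small populations die out globally", {
  p <- model_params(K = 3, lambda = 0, S = 2, P = 10)
  sim <- simulate_metacommunity(p, t_max = 2000, seed = 13)
  expect_equal(glance(sim)$n_extant_species, 0L)
  expect_equal(sum(sim$final_field), 0)
})

test_that("non-interacting species fluctuate independently", {
  p <- model_params(alpha = 0, lambda = 0.3, S = 2, P = 60, K = 10)
  sim <- simulate_metacommunity(p, t_max = 600, record_every = 2, seed = 14,
                                record_species = TRUE)
  x <- sim$species_mean[-(1:50), 1]
  y <- sim$species_mean[-(1:50), 2]
  expect_lt(abs(cor(x, y)), 0.25)
})

test_that("tidy, glance and autoplot work on simulations", {
  p <- model_params(S = 2, P = 20, lambda = 0.4)
  sim <- simulate_metacommunity(p, t_max = 50, seed = 15,
                                occupancy_species = 1L)
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("time", "mean_abundance", "mean_geff",
                     "n_extant_species", "mean_local_diversity"))
  gl <- glance(sim)
  expect_equal(nrow(gl), 1L)
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(autoplot(occupancy(sim, 1)), "ggplot")
})
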