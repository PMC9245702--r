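test_that("extinction runs are enumerated correctly on the ring", {
  # fully occupied slice: no runs
  expect_equal(nrow(extinction_run_lengths(matrix(TRUE, 3, 5))), 0L)
  # [1,0,0,1,0] with wraparound: runs of 2 and 1
  occ <- matrix(c(TRUE, FALSE, FALSE, TRUE, FALSE), 1, 5, byrow = TRUE)
  runs <- extinction_run_lengths(occ)
  expect_setequal(runs$length, c(2L, 1L))
  expect_false(any(runs$censored))
  # wrap-around run: [0,1,1,0,0] has one run of length 3 (patches 4,5,1)
  occ2 <- matrix(c(FALSE, TRUE, TRUE, FALSE, FALSE), 1, 5, byrow = TRUE)
  runs2 <- extinction_run_lengths(occ2)
  expect_equal(runs2$length, 3L)
  # fully extinct slice: one censored run of length P
  runs3 <- extinction_run_lengths(matrix(FALSE, 1, 5))
  expect_equal(runs3$length, 5L)
  expect_true(runs3$censored)
  # censored rows are excluded from fits but pooled rows accumulate
  occ4 <- rbind(c(TRUE, FALSE, FALSE, TRUE, TRUE),
                c(FALSE, FALSE, FALSE, FALSE, FALSE),
                c(TRUE, TRUE, FALSE, TRUE, TRUE))
  runs4 <- extinction_run_lengths(occ4)
  expect_equal(sort(runs4$length[!runs4$censored]), c(1L, 2L))
  expect_equal(runs4$length[runs4$censored], 5L)
})

test_that("recolonization intervals are measured and censored correctly", {
  # [3,0,0,0,2] at unit sampling: one interval of 3
  occ <- cbind(c(3, 0, 0, 0, 2)) > 0
  tt <- recolonization_times(occ)
  expect_equal(tt$tau, 3)
  expect_false(tt$censored)
  # never occupied: one censored interval
  tt2 <- recolonization_times(cbind(c(0, 0, 0)) > 0)
  expect_true(all(tt2$censored))
  # always occupied: nothing
  expect_equal(nrow(recolonization_times(cbind(c(1, 1, 1)) > 0)), 0L)
  # interval open at the end of the window is censored
  tt3 <- recolonization_times(cbind(c(1, 0, 0)) > 0)
  expect_true(all(tt3$censored))
  # sampling interval scales tau
  tt4 <- recolonization_times(cbind(c(3, 0, 0, 0, 2)) > 0, dt_sample = 5)
  expect_equal(tt4$tau, 15)
})

test_that("the maximum-likelihood fit recovers known exponents", {
  set.seed(101)
  for (a_true in c(1.747, 1.840)) {
    x <- rdiscrete_powerlaw(1e5, a_true, 1, 1000)
    fit <- fit_power_law(x, x_min = 1, x_max = 1000, n_boot = 100)
    expect_lt(abs(fit$exponent - a_true), 2 * fit$se)
    expect_true(fit$goodness_ok)
  }
})

test_that("the curvature diagnostic flags non-power-law samples", {
  set.seed(102)
  x <- rgeom(2e4, 0.05) + 1
  fit <- fit_power_law(x, x_min = 2, x_max = 150, n_boot = 20)
  expect_false(fit$goodness_ok)
})

test_that("fitting refuses too-small samples and degenerate ranges", {
  expect_error(fit_power_law(rep(5, 50), x_min = 2, x_max = 100),
               "need at least 100")
  expect_error(fit_power_law(rep(500, 300), x_min = 2, x_max = 100),
               "need at least 100")
})

test_that("tidy and glance expose the fit, autoplot draws it", {
  set.seed(103)
  x <- rdiscrete_powerlaw(5000, 2, 1, 300)
  fit <- fit_power_law(x, x_min = 1, x_max = 300, n_boot = 20)
  td <- tidy(fit)
  expect_equal(td$term, "exponent")
  expect_equal(td$estimate, fit$exponent)
  gl <- glance(fit)
  expect_named(gl, c("exponent", "se", "x_min", "x_max", "n", "curvature",
                     "goodness_ok"))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the straight-range selector shortens the window for curved tails", {
  set.seed(104)
  # power law with an exponential cutoff around 50
  x <- rdiscrete_powerlaw(5e4, 1.7, 1, 500)
  keep <- runif(length(x)) < exp(-x / 50)
  xc <- x[keep]
  xm_cut <- straight_fit_range(xc, x_min = 2)
  xp <- rdiscrete_powerlaw(5e4, 1.7, 1, 500)
  xm_pure <- straight_fit_range(xp, x_min = 2)
  expect_lt(xm_cut, xm_pure)
})

test_that("survival-based bisection reports a dispersal-limited phase", {
  # lambda = 0 cannot sustain the population at any g <= 1
  expect_error(estimate_gc(lambda = 0, K = 3, P = 10, t_max = 500,
                           n_rep = 4, tol = 0.1, seed = 3),
               "critical dispersal")
})

test_that("survival frequency increases with g across the bisection history", {
  est <- estimate_gc(lambda = 0.89, P = 100, t_max = 1000, n_rep = 8,
                     tol = 0.02, seed = 21)
  expect_true(est$gc > 0 && est$gc < 1)
  expect_true(est$lower < est$upper)
  h <- est$history[order(est$history$g), ]
  # monotone within binomial noise: allow one-step violations of 2 SE
  se2 <- 2 * sqrt(0.25 / 8)
  expect_true(all(diff(h$survival) > -2 * se2))
  # survival at the upper end, extinction at the lower end
  expect_gte(h$survival[nrow(h)], 0.5)
  expect_lt(h$survival[1], 0.5)
})
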