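test_that("the abundance density is normalized and rejects the degenerate limit", {
  for (lam in c(0.05, 0.1, 0.4)) {
    sol <- solve_self_consistent(lambda = lam, S = 5)
    total <- stats::integrate(function(N)
      abundance_density(N, sol$nbar, lambda = lam, S = 5), 0, 30,
      rel.tol = 1e-8)$value
    expect_equal(total, 1, tolerance = 1e-4)
  }
  expect_error(abundance_density(1, nbar = 0, lambda = 0.1), "Fisher")
  expect_error(abundance_density(1, nbar = 5, lambda = 0), "Fisher")
  expect_error(abundance_density(-1, nbar = 5, lambda = 0.1), "`N`")
})

test_that("large growth gives a Gaussian bulk with the predicted mode and variance", {
  # strong-K regime: mode at K (geff - lambda/r), variance K / (2 r)
  r <- 5; K <- 100; lam <- 0.01
  sol <- solve_self_consistent(r = r, K = K, lambda = lam, alpha = 0, S = 1)
  mom <- metacrit:::mf_moments(sol$nbar, r, K, lam, 0, 1)
  pred_mode <- K * (1 - lam / r)
  Ns <- seq(pred_mode - 20, pred_mode + 20, by = 0.02)
  d <- abundance_density(Ns, sol$nbar, r, K, lam, 0, 1)
  expect_lt(abs(Ns[which.max(d)] - pred_mode), 1)
  m2 <- stats::integrate(function(N)
    (N - mom$mean)^2 * abundance_density(N, sol$nbar, r, K, lam, 0, 1),
    0, K * 1.5, rel.tol = 1e-8)$value
  expect_equal(m2, K / (2 * r), tolerance = 0.05)
})

test_that("weak dispersal approaches the Fisher log-series shape", {
  # for lambda*nbar -> 0 the density approaches P(N) ~ x^N / N: after
  # multiplying by N, log P should be linear in N with slope log x = 2 r a
  r <- 0.3; K <- 10; lam <- 0.012
  sol <- solve_self_consistent(r = r, K = K, lambda = lam, alpha = 0, S = 1)
  expect_true(sol$nontrivial)
  eps <- 2 * lam * sol$nbar
  expect_lt(eps, 0.5) # genuinely in the near-singular regime
  a <- 1 - lam / r
  Ns <- c(0.5, 1, 1.5, 2, 2.5, 3)
  d <- abundance_density(Ns, sol$nbar, r, K, lam, 0, 1)
  y <- log(d * Ns)
  pred <- y[2] + 2 * r * a * (Ns - 1) # anchored at N = 1
  expect_lt(max(abs(y - pred)), 0.4)
  # and the N^-1 divergence is visible: density grows as N drops below 1
  expect_true(all(diff(abundance_density(c(0.05, 0.1, 0.3, 0.6), sol$nbar,
                                         r, K, lam, 0, 1)) < 0))
})

test_that("the self-consistent solution closes on itself", {
  for (S in c(1, 5, 50)) {
    sol <- solve_self_consistent(lambda = 0.1, S = S, tolerance = 1e-6)
    expect_true(sol$converged)
    expect_lt(sol$residual, 1e-6)
    mean_back <- stats::integrate(function(N)
      N * abundance_density(N, sol$nbar, lambda = 0.1, S = S), 0, 30,
      rel.tol = 1e-9)$value
    expect_equal(mean_back, sol$nbar, tolerance = 1e-3)
    expect_equal(sol$geff, 1 - 0.1 / 10 * (S - 1) * sol$nbar)
  }
})

test_that("the mean abundance bifurcates at the critical dispersal rate", {
  lc <- critical_dispersal(r = 0.3, K = 10)
  below <- solve_self_consistent(lambda = lc * 0.8, alpha = 0, S = 1)
  expect_false(below$nontrivial)
  expect_equal(below$nbar, 0)
  lams <- lc * c(1.2, 2, 5, 20)
  nbars <- vapply(lams, function(l)
    solve_self_consistent(lambda = l, alpha = 0, S = 1)$nbar, numeric(1))
  expect_true(all(nbars > 0))
  expect_true(all(diff(nbars) > 0)) # increasing above threshold
})

test_that("the dispersal threshold is independent of S and alpha", {
  lc1 <- critical_dispersal(r = 0.3, K = 10)
  # existence of a nonzero root at S = 100, alpha = 0.1 flips at the same point
  above <- solve_self_consistent(lambda = lc1 * 1.1, alpha = 0.1, S = 100)
  belowS <- solve_self_consistent(lambda = lc1 * 0.9, alpha = 0.1, S = 100)
  expect_true(above$nontrivial)
  expect_false(belowS$nontrivial)
})

test_that("the threshold decreases with Kr and matches the small-lambda asymptote", {
  grid <- expand.grid(r = c(0.3, 0.5), K = c(10, 14))
  grid$Kr <- grid$r * grid$K
  grid <- grid[order(grid$Kr), ]
  lcs <- mapply(function(r, K) critical_dispersal(r, K), grid$r, grid$K)
  expect_true(all(diff(lcs[order(grid$Kr)]) < 0))
  # log-scale agreement deep in the small-lambda regime
  for (i in which(grid$Kr >= 5)) {
    ratio <- lcs[i] / critical_dispersal_asymptote(grid$r[i], grid$K[i])
    expect_lt(abs(log(ratio)), 0.05)
  }
})

test_that("the critical growth factor decreases with dispersal and tends to 1 at the threshold", {
  lc <- critical_dispersal(r = 0.3, K = 10)
  gc_near <- critical_growth_factor_meanfield(lambda = lc * 1.05)
  expect_equal(gc_near, 1, tolerance = 0.02)
  lams <- c(0.01, 0.05, 0.1, 0.3)
  gcs <- vapply(lams, function(l)
    critical_growth_factor_meanfield(lambda = l), numeric(1))
  expect_true(all(diff(gcs) < 0))
  # survival at g = 1 for any lambda above threshold
  expect_true(solve_self_consistent(lambda = 0.05, alpha = 0, S = 1,
                                    g = 1)$nontrivial)
})

test_that("broom methods summarize mean-field solutions", {
  sol <- solve_self_consistent(lambda = 0.1, S = 5)
  expect_equal(tidy(sol)$estimate, c(sol$nbar, sol$geff))
  gl <- glance(sol)
  expect_true(gl$converged)
  expect_s3_class(autoplot(sol), "ggplot")
})
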