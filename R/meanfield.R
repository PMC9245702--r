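#' Mean-field species abundance density for global dispersal
#'
#' For global (all-to-all) dispersal the stationary abundance of one species
#' on one patch behaves like a particle in an effective potential set by the
#' community mean abundance `nbar`, with density
#' \deqn{P(N) = Z^{-1} N^{2 \lambda \bar{N} - 1}
#'   \exp\{-K r [(g_{eff} - \lambda/r) - N/K]^2\},}
#' where `g_eff = 1 - (alpha/K) (S - 1) nbar` is the mean-field effective
#' growth factor. For small `lambda * nbar` the power-law factor dominates
#' and the density approaches a Fisher log-series shape; for large `K r` it
#' approaches a Gaussian with mode `K (g_eff - lambda/r)` and variance
#' `K / (2 r)`. The normalization `Z` is computed by numerical quadrature
#' over `N` in (0, Inf); the integrable endpoint singularity `N^(eps - 1)` is
#' handled by the substitution `u = N^eps`.
#'
#' @param N Abundance value(s) at which to evaluate the density (> 0).
#' @param nbar Mean-field mean abundance (> 0; `lambda * nbar = 0` makes the
#'   density non-normalizable — the degenerate Fisher limit — and is
#'   rejected).
#' @param r,K,lambda,alpha,S Model parameters as in [model_params()].
#' @param g Optional fixed growth factor overriding the self-consistent
#'   `g_eff` (used for the single-species reference dynamics).
#' @return Numeric vector of density values (integrating to 1 over `N`).
#' @examples
#' abundance_density(5, nbar = 4.8, lambda = 0.1)
#' @export
abundance_density <- function(N, nbar, r = 0.3, K = 10, lambda = 0.1,
                              alpha = 0.1, S = 5, g = NULL) {
  if (any(N <= 0)) stop("`N` must be > 0", call. = FALSE)
  if (nbar < 0 || lambda < 0) stop("`nbar` and `lambda` must be >= 0",
                                   call. = FALSE)
  if (lambda * nbar <= 0)
    stop(paste0("lambda * nbar = 0: the N^(-1) endpoint makes the density ",
                "non-normalizable (degenerate Fisher limit)"), call. = FALSE)
  mom <- mf_moments(nbar, r, K, lambda, alpha, S, g)
  exp(mf_log_weight(N, mom$eps, mom$a, r, K) - mom$logZ)
}

# log of the unnormalized weight N^(eps-1) exp(-K r (a - N/K)^2)
mf_log_weight <- function(N, eps, a, r, K) {
  (eps - 1) * log(N) - K * r * (a - N / K)^2
}

# normalization Z and first moment of the mean-field weight.
# eps = 2 lambda nbar, a = g_eff - lambda / r.
mf_moments <- function(nbar, r, K, lambda, alpha, S, g = NULL) {
  eps <- 2 * lambda * nbar
  geff <- if (is.null(g)) 1 - (alpha / K) * (S - 1) * nbar else g
  a <- geff - lambda / r
  n_max <- max(K * geff, 0) + 10 * sqrt(K / (2 * r)) + 1

  # log of integral of N^p exp(-K r (a - N/K)^2) over (0, n_max], with the
  # peak value factored out for overflow safety
  log_int <- function(p) {
    n_star <- K * (a + sqrt(a^2 + 2 * p / (K * r))) / 2 # maximizer when p > 0
    lmax <- if (p > 0) p * log(n_star) - K * r * (a - n_star / K)^2
            else if (a > 0) 0 else -K * r * a^2
    v <- stats::integrate(function(N) {
      exp(p * log(N) - K * r * (a - N / K)^2 - lmax)
    }, 0, n_max, rel.tol = 1e-9, stop.on.error = FALSE)$value
    lmax + log(v)
  }
  logZ <- if (eps < 1) {
    # substitute u = N^eps to remove the integrable endpoint singularity
    zint <- function(u) exp(-K * r * (a - u^(1 / eps) / K)^2) / eps
    log(stats::integrate(zint, 0, n_max^eps, rel.tol = 1e-9,
                         stop.on.error = FALSE)$value)
  } else log_int(eps - 1)
  logM1 <- log_int(eps)
  list(eps = eps, a = a, geff = geff, logZ = logZ, Z = exp(logZ),
       mean = exp(logM1 - logZ), n_max = n_max)
}

#' Solve the mean-field self-consistency condition
#'
#' Under global dispersal the migrant pool is generated by the metacommunity
#' itself, so the mean abundance entering [abundance_density()] must equal
#' the mean of that density. This function locates the roots of
#' `F(nbar) = <N>(nbar) - nbar`. `nbar = 0` (global extinction) is always a
#' root; below the critical dispersal rate it is the only one, and above it
#' a nonzero root appears, whose largest (stable) representative is
#' returned.
#'
#' @inheritParams abundance_density
#' @param tolerance Relative self-consistency tolerance.
#' @return An object of class `"meanfield_solution"`: a list with the mean
#'   abundance `nbar` (0 if only the trivial root exists), the mean-field
#'   effective growth factor `geff`, normalization `Z`, the residual
#'   `|<N> - nbar|`, a `converged` flag, and the parameter set.
#' @examples
#' solve_self_consistent(lambda = 0.1, S = 5)
#' @export
solve_self_consistent <- function(r = 0.3, K = 10, lambda = 0.1, alpha = 0.1,
                                  S = 5, g = NULL, tolerance = 1e-6) {
  stopifnot(r > 0, K > 0, lambda >= 0, alpha >= 0, S >= 1)
  trivial <- structure(
    list(nbar = 0, geff = if (is.null(g)) 1 else g, Z = NA_real_,
         residual = 0, converged = TRUE, nontrivial = FALSE,
         r = r, K = K, lambda = lambda, alpha = alpha, S = S),
    class = "meanfield_solution")
  if (lambda == 0) return(trivial)
  f <- function(nbar) mf_moments(nbar, r, K, lambda, alpha, S, g)$mean - nbar
  n_hi <- 1.05 * K * max(1, if (is.null(g)) 1 else g)
  grid <- c(10^seq(-9, -1, length.out = 12),
            seq(0.15, n_hi, length.out = 50))
  fv <- vapply(grid, f, numeric(1))
  sgn <- sign(fv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(flips)) return(trivial)
  i <- flips[length(flips)] # largest root = stable branch
  root <- stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)
  nbar <- root$root
  mom <- mf_moments(nbar, r, K, lambda, alpha, S, g)
  residual <- abs(mom$mean - nbar) / max(nbar, 1)
  structure(list(nbar = nbar, geff = mom$geff, Z = mom$Z,
                 residual = residual, converged = residual < tolerance,
                 nontrivial = TRUE,
                 r = r, K = K, lambda = lambda, alpha = alpha, S = S),
            class = "meanfield_solution")
}

#' @export
print.meanfield_solution <- function(x, ...) {
  cat(sprintf("<meanfield_solution> nbar = %.6g, geff = %.6g (lambda = %g, S = %g)\n",
              x$nbar, x$geff, x$lambda, x$S))
  if (x$nontrivial)
    cat(sprintf("  residual %.2g (%s)\n", x$residual,
                if (x$converged) "converged" else "NOT converged"))
  else cat("  only the trivial root nbar = 0 (below the dispersal threshold)\n")
  invisible(x)
}

#' @method tidy meanfield_solution
#' @export
tidy.meanfield_solution <- function(x, ...) {
  tibble::tibble(term = c("nbar", "geff"), estimate = c(x$nbar, x$geff))
}

#' @method glance meanfield_solution
#' @export
glance.meanfield_solution <- function(x, ...) {
  tibble::tibble(nbar = x$nbar, geff = x$geff, residual = x$residual,
                 converged = x$converged, nontrivial = x$nontrivial,
                 r = x$r, K = x$K, lambda = x$lambda, alpha = x$alpha,
                 S = x$S)
}

#' @method autoplot meanfield_solution
#' @export
autoplot.meanfield_solution <- function(object, ...) {
  if (!object$nontrivial)
    stop("nothing to plot: only the trivial root exists", call. = FALSE)
  Ns <- seq(0.01, object$K * 1.3, length.out = 400)
  d <- abundance_density(Ns, object$nbar, object$r, object$K, object$lambda,
                         object$alpha, object$S)
  ggplot2::ggplot(tibble::tibble(N = Ns, density = d),
                  ggplot2::aes(.data$N, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "abundance N", y = "P(N)")
}

#' Critical dispersal rate of the mean-field theory
#'
#' Locates the bifurcation point of the self-consistency condition: the
#' dispersal rate below which only the trivial root `nbar = 0` exists and
#' above which a nonzero mean abundance appears. Computed for the
#' single-species case by bisection on `lambda` of the indicator "a nonzero
#' self-consistent root exists"; because the competition term enters the
#' condition only through `g_eff`, which tends to 1 as `nbar` tends to 0,
#' the result is independent of `alpha` and `S`.
#'
#' For `K * lambda << K * r` the threshold has the closed small-dispersal
#' asymptote `lambda_c ~ exp(-K r) * sqrt(r / (4 pi K))` (see
#' [critical_dispersal_asymptote()]).
#'
#' @inheritParams abundance_density
#' @param tolerance Absolute bisection tolerance on `lambda` relative to its
#'   magnitude.
#' @return The critical dispersal rate (per generation).
#' @examples
#' \donttest{critical_dispersal(r = 0.3, K = 10)}
#' @export
critical_dispersal <- function(r = 0.3, K = 10, tolerance = 1e-4) {
  has_root <- function(lam)
    solve_self_consistent(r, K, lam, alpha = 0, S = 1)$nontrivial
  lo <- NA; hi <- NA
  for (lam in 10^seq(-10, 1, by = 1)) {
    if (!has_root(lam)) lo <- lam else { hi <- lam; break }
  }
  if (is.na(lo) || is.na(hi))
    stop("failed to bracket the dispersal threshold", call. = FALSE)
  while ((hi - lo) / hi > tolerance) {
    mid <- sqrt(lo * hi)
    if (has_root(mid)) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

#' Small-dispersal asymptote of the critical dispersal rate
#'
#' Closed-form approximation `lambda_c ~ exp(-K r) * sqrt(r / (4 pi K))`,
#' valid in the regime `K * lambda << K * r` where local populations sit in a
#' deep effective potential well and global extinction is driven by rare
#' fluctuations; it follows from expanding the self-consistency condition of
#' [solve_self_consistent()] around `nbar = 0`.
#'
#' @inheritParams abundance_density
#' @return Approximate critical dispersal rate.
#' @export
critical_dispersal_asymptote <- function(r = 0.3, K = 10) {
  exp(-K * r) * sqrt(r / (4 * pi * K))
}

#' Mean-field critical growth factor
#'
#' For the single-species reference dynamics with fixed growth factor `g`
#' under global dispersal, locates by bisection the `g` at which the nonzero
#' self-consistent root appears. For `lambda` just above the critical
#' dispersal rate the threshold approaches 1 (the bare dynamics are then
#' exactly marginal), and it decreases with increasing dispersal.
#'
#' @inheritParams abundance_density
#' @param tolerance Absolute bisection tolerance on `g`.
#' @return The critical growth factor (dimensionless).
#' @examples
#' \donttest{critical_growth_factor_meanfield(lambda = 0.1)}
#' @export
critical_growth_factor_meanfield <- function(r = 0.3, K = 10, lambda = 0.1,
                                             tolerance = 1e-4) {
  has_root <- function(g)
    solve_self_consistent(r, K, lambda, alpha = 0, S = 1, g = g)$nontrivial
  lo <- 0; hi <- 2
  if (!has_root(hi))
    stop(sprintf("no nonzero root even at g = %g: lambda below lambda_c?", hi),
         call. = FALSE)
  if (has_root(lo)) return(lo)
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (has_root(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
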