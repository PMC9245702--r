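#' Extinction-cluster lengths of a spatiotemporal occupancy pattern
#'
#' For every sampled time slice, finds the maximal runs of contiguous extinct
#' patches on the periodic ring (a run may wrap around the boundary). A slice
#' in which the species is absent from every patch yields a single run of
#' length `P` flagged as censored (its true extent is not observable on the
#' ring); all other runs are uncensored. Run lengths are pooled across
#' slices.
#'
#' @param occ A time x patch logical (or 0/1) matrix, `TRUE` = present;
#'   typically from [occupancy()].
#' @return A tibble with columns `length` (patches) and `censored`.
#' @examples
#' occ <- rbind(c(TRUE, FALSE, FALSE, TRUE, FALSE),
#'              c(TRUE, TRUE, TRUE, TRUE, TRUE))
#' extinction_run_lengths(occ) # wrapping run of 1, interior run of 2
#' @export
extinction_run_lengths <- function(occ) {
  occ <- as.matrix(occ) > 0
  P <- ncol(occ)
  if (P < 2) stop("need at least 2 patches", call. = FALSE)
  res <- lapply(seq_len(nrow(occ)), function(t) {
    extinct <- !occ[t, ]
    if (!any(extinct)) return(NULL)
    if (all(extinct)) return(c(P, 1))
    rl <- rle(extinct)
    len <- rl$lengths[rl$values]
    # merge the wrap-around run when both ends of the row are extinct
    if (extinct[1] && extinct[P]) {
      n <- length(len)
      len <- if (n == 1) len else c(len[1] + len[n], len[2:(n - 1)][seq_len(n - 2)])
    }
    cbind(len, 0)
  })
  m <- do.call(rbind, res)
  if (is.null(m)) m <- matrix(numeric(0), 0, 2)
  tibble::tibble(length = as.integer(m[, 1]), censored = m[, 2] == 1)
}

#' Recolonization times of a spatiotemporal occupancy pattern
#'
#' For every patch, each maximal interval of consecutive extinct samples that
#' is bounded by occupied samples on both sides contributes a recolonization
#' time `tau` equal to the interval length times the sampling interval.
#' Intervals that touch the start or end of the observation window are
#' censored (the extinction or recolonization endpoint was not observed) and
#' excluded from fitted samples.
#'
#' @inheritParams extinction_run_lengths
#' @param dt_sample Sampling interval in generations; defaults to the
#'   `dt_sample` attribute of `occ` or 1.
#' @return A tibble with columns `tau` (generations) and `censored`.
#' @examples
#' occ <- cbind(c(3, 0, 0, 0, 2)) > 0 # one patch, tau = 3
#' recolonization_times(occ)
#' @export
recolonization_times <- function(occ, dt_sample = NULL) {
  if (is.null(dt_sample)) dt_sample <- attr(occ, "dt_sample") %||% 1
  occ <- as.matrix(occ) > 0
  if (nrow(occ) < 2) stop("need at least 2 time samples", call. = FALSE)
  Tn <- nrow(occ)
  res <- lapply(seq_len(ncol(occ)), function(x) {
    extinct <- !occ[, x]
    if (!any(extinct)) return(NULL)
    rl <- rle(extinct)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    keep <- rl$values
    cbind(rl$lengths[keep], starts[keep] == 1 | ends[keep] == Tn)
  })
  m <- do.call(rbind, res)
  if (is.null(m)) m <- matrix(numeric(0), 0, 2)
  tibble::tibble(tau = m[, 1] * dt_sample, censored = m[, 2] == 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a discrete power law by maximum likelihood
#'
#' Fits `P(x) proportional to x^(-a)` to integer-valued samples on the range
#' `[x_min, x_max]` by maximizing the truncated discrete (zeta) likelihood.
#' Samples outside the range are discarded before fitting. The standard error
#' is obtained by bootstrap resampling of the retained samples. As a goodness
#' diagnostic, a quadratic term is added to the straight-line fit of the
#' log-binned histogram in log-log coordinates; pronounced curvature
#' (|z| > 3) flags distributions, such as geometric ones, that are not
#' scale-free over the fitted range.
#'
#' @param x Integer samples (e.g. cluster lengths or recolonization times).
#' @param x_min Lower end of the fit range (default 2; the single-site bin is
#'   dominated by lattice discreteness).
#' @param x_max Upper end of the fit range, or `NULL` to use the largest
#'   value such that every log-spaced bin up to it holds at least
#'   `min_bin_count` samples.
#' @param n_boot Bootstrap replicates for the standard error.
#' @param min_bin_count Occupancy threshold used when choosing `x_max`
#'   automatically.
#' @return An object of class `"power_law_fit"` with the exponent magnitude
#'   `exponent` (so the fitted slope on a log-log plot is `-exponent`), its
#'   bootstrap `se`, the fit range, sample count `n`, the curvature
#'   diagnostic, and the log-binned histogram used for plotting.
#' @examples
#' x <- sample(1:100, 500, replace = TRUE, prob = (1:100)^-1.7)
#' fit_power_law(x, x_min = 1, x_max = 100, n_boot = 20)
#' @export
fit_power_law <- function(x, x_min = 2, x_max = NULL, n_boot = 200,
                          min_bin_count = 10) {
  x <- as.numeric(x[is.finite(x)])
  x <- round(x)
  if (is.null(x_max)) x_max <- auto_xmax(x, x_min, min_bin_count)
  x <- x[x >= x_min & x <= x_max]
  n <- length(x)
  if (n < 100)
    stop(sprintf("only %d samples in [%g, %g]; need at least 100", n,
                 x_min, x_max), call. = FALSE)

  mle <- function(xs) {
    slx <- sum(log(xs))
    ks <- x_min:x_max
    lks <- log(ks)
    nll <- function(a) a * slx + length(xs) * log(sum(exp(-a * lks)))
    stats::optimize(nll, c(0.01, 8))$minimum
  }
  a_hat <- mle(x)
  boots <- replicate(n_boot, mle(sample(x, n, replace = TRUE)))
  se <- stats::sd(boots)

  bins <- log_binned_density(x, x_min, x_max)
  curvature <- curvature_diagnostic(bins)

  structure(list(exponent = a_hat, se = se, x_min = x_min, x_max = x_max,
                 n = n, curvature = curvature,
                 goodness_ok = is.finite(curvature) && abs(curvature) < 3,
                 bins = bins, boot = boots),
            class = "power_law_fit")
}

log_edges <- function(x_min) unique(round(x_min * 2^(0:80 / 4)))

# largest x such that all log-spaced bins from x_min up to it hold at least
# min_count samples (contiguously from the first bin)
auto_xmax <- function(x, x_min, min_count) {
  x <- x[x >= x_min]
  if (!length(x)) return(x_min + 9)
  edges <- log_edges(x_min)
  cnt <- tabulate(findInterval(x, edges), nbins = length(edges) - 1)
  bad <- which(cnt < min_count)
  last <- if (length(bad)) bad[1] - 1 else max(which(cnt > 0))
  if (last < 1) return(x_min + 9)
  max(edges[last + 1] - 1, x_min + 9)
}

log_binned_density <- function(x, x_min, x_max) {
  edges <- log_edges(x_min)
  edges <- c(edges[edges <= x_max], x_max + 1)
  if (length(edges) < 3)
    edges <- unique(round(seq(x_min, x_max + 1, length.out = 4)))
  cnt <- tabulate(findInterval(x, edges), nbins = length(edges) - 1)
  width <- diff(edges)
  mid <- exp((log(edges[-length(edges)]) + log(pmax(edges[-1] - 1,
                                                    edges[-length(edges)]))) / 2)
  tibble::tibble(x = mid, density = cnt / width / length(x), count = cnt)
}

# z-statistic of the quadratic coefficient of log density ~ log x + (log x)^2
curvature_diagnostic <- function(bins) {
  b <- bins[bins$count > 0, ]
  if (nrow(b) < 4) return(NA_real_)
  lx <- log(b$x); ly <- log(b$density)
  fit <- stats::lm(ly ~ lx + I(lx^2), weights = b$count)
  cf <- summary(fit)$coefficients
  if (nrow(cf) < 3 || !is.finite(cf[3, 2]) || cf[3, 2] == 0) return(NA_real_)
  cf[3, 1] / cf[3, 2]
}

#' Choose the upper end of the scaling range by a straightness criterion
#'
#' Scans candidate upper cutoffs (log-bin edges) and, for each, evaluates the
#' curvature diagnostic of the log-binned histogram on `[x_min, x_max]`. The
#' largest cutoff whose curvature z-statistic stays within `z_max` is
#' returned, i.e. the widest window over which the log-binned counts are
#' straight; if no candidate qualifies, the candidate with the smallest
#' curvature magnitude is used.
#'
#' @inheritParams fit_power_law
#' @param z_max Curvature tolerance (z-statistic of the quadratic term).
#' @return The selected `x_max`.
#' @export
straight_fit_range <- function(x, x_min = 2, z_max = 2, min_bin_count = 10) {
  x <- round(as.numeric(x[is.finite(x)]))
  hard_max <- auto_xmax(x, x_min, min_bin_count)
  edges <- log_edges(x_min)
  cand <- edges[edges > x_min * 8 & edges <= hard_max]
  if (!length(cand)) return(hard_max)
  zs <- vapply(cand, function(xm) {
    xs <- x[x >= x_min & x <= xm]
    if (length(xs) < 100) return(NA_real_)
    abs(curvature_diagnostic(log_binned_density(xs, x_min, xm)))
  }, numeric(1))
  ok <- which(is.finite(zs) & zs <= z_max)
  if (length(ok)) cand[max(ok)]
  else if (any(is.finite(zs))) cand[which.min(zs)]
  else hard_max
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> exponent = %.3f (se %.3f), range [%g, %g], n = %d\n",
              x$exponent, x$se, x$x_min, x$x_max, x$n))
  cat(sprintf("  curvature z = %.2f (%s)\n", x$curvature,
              if (isTRUE(x$goodness_ok)) "consistent with a power law"
              else "curved: power law questionable"))
  invisible(x)
}

#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(term = "exponent", estimate = x$exponent, std.error = x$se)
}

#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(exponent = x$exponent, se = x$se, x_min = x$x_min,
                 x_max = x$x_max, n = x$n, curvature = x$curvature,
                 goodness_ok = x$goodness_ok)
}

#' @method autoplot power_law_fit
#' @export
autoplot.power_law_fit <- function(object, ...) {
  b <- object$bins[object$bins$count > 0, ]
  ref <- tibble::tibble(
    x = c(object$x_min, object$x_max),
    density = b$density[1] * (c(object$x_min, object$x_max) / b$x[1])^
      (-object$exponent))
  ggplot2::ggplot(b, ggplot2::aes(.data$x, .data$density)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = ref, linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "x", y = "P(x)",
                  subtitle = sprintf("fitted exponent %.3f (se %.3f)",
                                     object$exponent, object$se))
}

#' Estimate the critical growth factor of the single-species dynamics
#'
#' Locates the absorbing-state transition of the decoupled single-species
#' lattice dynamics (see [simulate_single_species()]) by bisection on the
#' fixed growth factor `g`. At each candidate `g`, `n_rep` replicate runs of
#' `t_max` generations start from the standard initial condition and are
#' classified as surviving if any patch is occupied at the final time; the
#' estimate is the point where the survival frequency crosses 1/2. Finite
#' `t_max` and `P` make this an effective (slightly protocol-dependent)
#' threshold, which is reported together with its final bracketing interval.
#'
#' @inheritParams simulate_single_species
#' @param t_max Classification horizon in generations.
#' @param n_rep Replicates per candidate `g`.
#' @param tol Half-width of the final bracket on `g`.
#' @param g_range Initial bracket; the upper end should survive and the lower
#'   end die out.
#' @return An object of class `"gc_estimate"`: a list with `gc`, `lower`,
#'   `upper`, and a `history` tibble of (g, survival frequency).
#' @examples
#' \donttest{
#' est <- estimate_gc(lambda = 0.4, P = 100, t_max = 1000, n_rep = 5,
#'                    tol = 0.05, seed = 1)
#' }
#' @export
estimate_gc <- function(r = 0.3, K = 10, lambda = 0.89, P = 200L, dt = 0.1,
                        topology = "nearest_neighbor_1d",
                        t_max = 1e4, n_rep = 20, tol = 0.01,
                        g_range = c(0.1, 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  survival_freq <- function(g) {
    alive <- vapply(seq_len(n_rep), function(k) {
      sim <- simulate_single_species(g = g, r = r, K = K, lambda = lambda,
                                     P = P, dt = dt, topology = topology,
                                     t_max = t_max, record_every = t_max,
                                     record_occupancy = FALSE)
      sum(sim$final_field) > 0
    }, logical(1))
    mean(alive)
  }
  lo <- g_range[1]; hi <- g_range[2]
  history <- list()
  f_hi <- survival_freq(hi)
  history[[length(history) + 1]] <- c(hi, f_hi)
  if (f_hi < 0.5)
    stop(sprintf(paste0("no survival even at g = %g: lambda = %g appears to ",
                        "be at or below the critical dispersal rate"),
                 hi, lambda), call. = FALSE)
  f_lo <- survival_freq(lo)
  history[[length(history) + 1]] <- c(lo, f_lo)
  if (f_lo >= 0.5)
    stop(sprintf("survival already at g = %g; lower `g_range`", lo),
         call. = FALSE)
  while (hi - lo > 2 * tol) {
    mid <- (lo + hi) / 2
    f_mid <- survival_freq(mid)
    history[[length(history) + 1]] <- c(mid, f_mid)
    if (f_mid >= 0.5) hi <- mid else lo <- mid
  }
  hist_df <- do.call(rbind, history)
  structure(list(gc = (lo + hi) / 2, lower = lo, upper = hi,
                 history = tibble::tibble(g = hist_df[, 1],
                                          survival = hist_df[, 2]),
                 r = r, K = K, lambda = lambda, P = P, t_max = t_max,
                 n_rep = n_rep),
            class = "gc_estimate")
}

#' Near-critical pattern statistics of the single-species lattice dynamics
#'
#' The headline pattern protocol in one call: estimate the critical growth
#' factor by survival bisection ([estimate_gc()]), run the single-species
#' lattice just above it (`g = upper bracket + margin`, inside the surviving
#' phase but close to criticality), discard a burn-in, and pool
#' extinction-cluster lengths and recolonization times over the analysis
#' window. Because a single near-critical run can go globally extinct early
#' for unlucky seeds, fresh replicate runs are added (up to `max_rep`) until
#' the pooled uncensored length sample reaches `min_lengths`; runs that die
#' early contribute whatever window they produced.
#'
#' @inheritParams simulate_single_species
#' @param t_max Generations per replicate run.
#' @param burn_in Generations discarded at the start of each run.
#' @param g Fixed growth factor; `NULL` (default) estimates `g_c` first.
#' @param margin Offset above the bisection bracket's upper edge.
#' @param max_rep Maximum number of replicate runs to pool.
#' @param min_lengths Target number of pooled uncensored cluster lengths.
#' @param gc_t_max,gc_n_rep,gc_tol Protocol of the embedded [estimate_gc()]
#'   call.
#' @return A list with the growth factor `g` used, the `gc_estimate` (if
#'   computed), pooled uncensored `lengths` and `taus`, and `n_runs`.
#' @export
critical_pattern_statistics <- function(r = 0.3, K = 10, lambda = 0.89,
                                        P = 1000L, dt = 0.1,
                                        t_max = 5e4, burn_in = 1e4,
                                        g = NULL, margin = 0.012,
                                        max_rep = 4, min_lengths = 2e5,
                                        gc_t_max = 1e4, gc_n_rep = 6,
                                        gc_tol = 0.005, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  est <- NULL
  if (is.null(g)) {
    est <- estimate_gc(r = r, K = K, lambda = lambda, P = P, dt = dt,
                       t_max = gc_t_max, n_rep = gc_n_rep, tol = gc_tol)
    g <- est$upper + margin
  }
  lengths <- integer(0)
  taus <- numeric(0)
  n_runs <- 0L
  while (n_runs < max_rep && length(lengths) < min_lengths) {
    sim <- simulate_single_species(g = g, r = r, K = K, lambda = lambda,
                                   P = P, dt = dt, t_max = t_max,
                                   record_every = 1)
    occ <- occupancy(sim)
    occ <- occ[attr(occ, "time") > burn_in, , drop = FALSE]
    ll <- extinction_run_lengths(occ)
    tt <- recolonization_times(occ, dt_sample = 1)
    lengths <- c(lengths, ll$length[!ll$censored])
    taus <- c(taus, tt$tau[!tt$censored])
    n_runs <- n_runs + 1L
  }
  list(g = g, gc = est, lengths = lengths, taus = taus, n_runs = n_runs)
}

#' @export
print.gc_estimate <- function(x, ...) {
  cat(sprintf("<gc_estimate> g_c = %.4f (bracket [%.4f, %.4f]) at lambda = %g\n",
              x$gc, x$lower, x$upper, x$lambda))
  cat(sprintf("  protocol: P = %d, t_max = %g generations, %d replicates per g\n",
              x$P, x$t_max, x$n_rep))
  invisible(x)
}

#' @method tidy gc_estimate
#' @export
tidy.gc_estimate <- function(x, ...) {
  tibble::tibble(term = "g_c", estimate = x$gc, lower = x$lower,
                 upper = x$upper)
}

#' @method glance gc_estimate
#' @export
glance.gc_estimate <- function(x, ...) {
  tibble::tibble(gc = x$gc, lower = x$lower, upper = x$upper,
                 lambda = x$lambda, r = x$r, K = x$K, P = x$P,
                 t_max = x$t_max, n_rep = x$n_rep)
}
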