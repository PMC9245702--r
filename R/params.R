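#' Model parameters for the metacommunity dynamics
#'
#' Bundles the homogeneous parameters of the stochastic Lotka-Volterra
#' metacommunity: `S` species on `P` patches, each species growing logistically
#' at rate `r` toward carrying capacity `K`, suppressed by every other species
#' on the same patch with (relative) competition strength `alpha`, and coupled
#' by dispersal at rate `lambda`, either between nearest neighbours on a
#' periodic 1D lattice or uniformly between all patches. Demographic noise is
#' implemented by the integrator's once-per-generation Poisson redraw (see
#' [simulate_metacommunity()]), giving noise variance equal to the abundance
#' per generation (amplitude omega = 1); time is measured in generations
#' (units of 1/omega) and `dt` is the Euler substep used for the
#' deterministic drift within a generation.
#'
#' @param r Per-capita growth rate (per generation), > 0.
#' @param K Carrying capacity (individuals per patch per species), > 0.
#' @param alpha Interspecies competition strength relative to self-limitation
#'   (dimensionless, >= 0). Weak competition means `0 < alpha << 1`.
#' @param lambda Dispersal rate (per generation), >= 0.
#' @param S Number of species (>= 1).
#' @param P Number of patches (>= 1).
#' @param topology `"nearest_neighbor_1d"` (periodic ring) or `"global"`.
#' @param dt Euler substep in generations; must divide one generation evenly.
#'
#' @return An object of class `"model_params"` (a named list).
#' @examples
#' model_params(lambda = 0.4, S = 5, P = 100)
#' @export
model_params <- function(r = 0.3, K = 10, alpha = 0.1, lambda = 0.4,
                         S = 1L, P = 100L,
                         topology = c("nearest_neighbor_1d", "global"),
                         dt = 0.1) {
  topology <- match.arg(topology)
  stop_if_bad <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  stop_if_bad(is.numeric(r) && length(r) == 1 && is.finite(r) && r > 0,
              "`r` must be a single positive number")
  stop_if_bad(is.numeric(K) && length(K) == 1 && is.finite(K) && K > 0,
              "`K` must be a single positive number")
  stop_if_bad(is.numeric(alpha) && length(alpha) == 1 && is.finite(alpha) &&
                alpha >= 0, "`alpha` must be a single number >= 0")
  stop_if_bad(is.numeric(lambda) && length(lambda) == 1 && is.finite(lambda) &&
                lambda >= 0, "`lambda` must be a single number >= 0")
  stop_if_bad(is.numeric(dt) && length(dt) == 1 && is.finite(dt) && dt > 0,
              "`dt` must be a single positive number")
  S <- as.integer(S); P <- as.integer(P)
  stop_if_bad(length(S) == 1 && !is.na(S) && S >= 1, "`S` must be an integer >= 1")
  stop_if_bad(length(P) == 1 && !is.na(P) && P >= 1, "`P` must be an integer >= 1")
  structure(list(r = r, K = K, alpha = alpha, lambda = lambda,
                 S = S, P = P, topology = topology, dt = dt),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  r = %g, K = %g, alpha = %g, lambda = %g\n",
              x$r, x$K, x$alpha, x$lambda))
  cat(sprintf("  S = %d species, P = %d patches, topology = %s, dt = %g\n",
              x$S, x$P, x$topology, x$dt))
  invisible(x)
}

#' Per-species heterogeneous parameters
#'
#' Container for species-specific growth rates `r_i`, dispersal rates
#' `lambda_i` and the pairwise interaction matrix `alpha_ij` (diagonal unused)
#' that generalize the homogeneous dynamics. Usually produced by
#' [draw_heterogeneous_params()].
#'
#' @param r_i Numeric vector of length `S` of per-species growth rates (> 0).
#' @param lambda_i Numeric vector of length `S` of dispersal rates (>= 0).
#' @param alpha_ij `S x S` numeric interaction matrix; entry `(i, j)` scales
#'   the suppression of species `i` by species `j`. The diagonal is ignored.
#' @param sigma_r,sigma_alpha,sigma_lambda Standard deviations of the
#'   generating normal distributions (metadata, may be `NA`).
#'
#' @return An object of class `"heterogeneous_params"`.
#' @export
heterogeneous_params <- function(r_i, lambda_i, alpha_ij,
                                 sigma_r = NA_real_, sigma_alpha = NA_real_,
                                 sigma_lambda = NA_real_) {
  S <- length(r_i)
  if (length(lambda_i) != S)
    stop("`r_i` and `lambda_i` must have the same length", call. = FALSE)
  alpha_ij <- as.matrix(alpha_ij)
  if (!all(dim(alpha_ij) == c(S, S)))
    stop("`alpha_ij` must be an S x S matrix", call. = FALSE)
  if (any(!is.finite(r_i)) || any(r_i <= 0))
    stop("all `r_i` must be finite and > 0", call. = FALSE)
  if (any(!is.finite(lambda_i)) || any(lambda_i < 0))
    stop("all `lambda_i` must be finite and >= 0", call. = FALSE)
  structure(list(r_i = as.numeric(r_i), lambda_i = as.numeric(lambda_i),
                 alpha_ij = alpha_ij, sigma_r = sigma_r,
                 sigma_alpha = sigma_alpha, sigma_lambda = sigma_lambda),
            class = "heterogeneous_params")
}

#' @export
print.heterogeneous_params <- function(x, ...) {
  cat(sprintf("<heterogeneous_params> S = %d\n", length(x$r_i)))
  cat(sprintf("  r_i in [%.3g, %.3g]; lambda_i in [%.3g, %.3g]\n",
              min(x$r_i), max(x$r_i), min(x$lambda_i), max(x$lambda_i)))
  cat(sprintf("  sigma_r = %g, sigma_alpha = %g, sigma_lambda = %g\n",
              x$sigma_r, x$sigma_alpha, x$sigma_lambda))
  invisible(x)
}

#' Draw species-specific parameters around the homogeneous values
#'
#' Growth rates, dispersal rates and pairwise interaction strengths are drawn
#' independently from normal distributions centred on the homogeneous values
#' `r`, `lambda` and `alpha` with standard deviations `sigma_r`,
#' `sigma_lambda` and `sigma_alpha`. Negative dispersal draws are replaced by
#' `lambda`; negative (or zero) growth-rate draws are replaced by `r`, the
#' analogous sanitization. Off-diagonal `alpha_ij` entries are drawn
#' independently for each ordered pair, so the interaction matrix is generally
#' asymmetric; negative interaction draws are kept (they act as weak
#' facilitation).
#'
#' @param params A [model_params()] object supplying the central values and `S`.
#' @param sigma_r,sigma_alpha,sigma_lambda Standard deviations (>= 0) of the
#'   generating normals.
#'
#' @return A [heterogeneous_params()] object.
#' @examples
#' p <- model_params(lambda = 0.4, S = 10, P = 50)
#' draw_heterogeneous_params(p, sigma_alpha = 0.5 / p$S, sigma_lambda = 0.03)
#' @export
draw_heterogeneous_params <- function(params, sigma_r = 0, sigma_alpha = 0,
                                      sigma_lambda = 0) {
  stopifnot(inherits(params, "model_params"))
  if (any(c(sigma_r, sigma_alpha, sigma_lambda) < 0))
    stop("sigmas must be >= 0", call. = FALSE)
  S <- params$S
  r_i <- stats::rnorm(S, params$r, sigma_r)
  r_i[r_i <= 0] <- params$r
  lambda_i <- stats::rnorm(S, params$lambda, sigma_lambda)
  lambda_i[lambda_i < 0] <- params$lambda
  alpha_ij <- matrix(stats::rnorm(S * S, params$alpha, sigma_alpha), S, S)
  diag(alpha_ij) <- 0
  heterogeneous_params(r_i, lambda_i, alpha_ij,
                       sigma_r = sigma_r, sigma_alpha = sigma_alpha,
                       sigma_lambda = sigma_lambda)
}
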