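#' Deterministic coexistence abundance
#'
#' Abundance of the symmetric fixed point at which all `S` species coexist on
#' every patch: `K / (1 + alpha * (S - 1))`. For `alpha = 0` species decouple
#' and the fixed point is the single-species carrying capacity; for
#' `alpha > 0` it decreases as more species are packed onto a patch.
#'
#' @param K Carrying capacity (> 0).
#' @param alpha Competition strength (>= 0).
#' @param S Number of species (>= 1).
#' @return The fixed-point abundance (numeric scalar, vectorized over inputs).
#' @examples
#' equilibrium_abundance(K = 10, alpha = 0.1, S = 5) # 10 / 1.4
#' @export
equilibrium_abundance <- function(K, alpha, S) {
  if (any(K <= 0)) stop("`K` must be > 0", call. = FALSE)
  if (any(alpha < 0)) stop("`alpha` must be >= 0", call. = FALSE)
  if (any(S < 1)) stop("`S` must be >= 1", call. = FALSE)
  K / (1 + alpha * (S - 1))
}

# competition load sum_{j != i} alpha_ij * N_{x,j}, P x S matrix
competition_load <- function(field, params, het = NULL) {
  if (is.null(het)) {
    params$alpha * (rowSums(field) - field)
  } else {
    A <- het$alpha_ij
    diag(A) <- 0
    field %*% t(A)
  }
}

#' Effective growth factor
#'
#' The effective growth factor of species `i` on patch `x` is the ratio of its
#' per-capita low-density growth rate in the presence of competitors to the
#' competitor-free rate: `1 - (alpha/K) * sum_{j != i} N_{x,j}` in the
#' homogeneous model, and `1 - (r / r_i) * sum_{j != i} alpha_ij N_{x,j} / K`
#' with heterogeneous parameters. It equals 1 exactly on patches with no
#' competitors and is `<= 1` whenever abundances and interactions are
#' nonnegative.
#'
#' @param field Integer abundance matrix (`P x S`), patches in rows.
#' @param params A [model_params()] object.
#' @param het Optional [heterogeneous_params()] object.
#' @return A `P x S` matrix of effective growth factors.
#' @examples
#' p <- model_params(S = 2, P = 3)
#' f <- matrix(c(0, 10, 5, 10, 0, 5), nrow = 3)
#' effective_growth_factor(f, p)
#' @export
effective_growth_factor <- function(field, params, het = NULL) {
  field <- check_field(field, params)
  comp <- competition_load(field, params, het)
  if (is.null(het)) 1 - comp / params$K
  else sweep(comp / params$K, 2, params$r / het$r_i, `*`) * -1 + 1
}

# dispersal increment for every entry, P x S
dispersal_term <- function(field, params, het = NULL) {
  lam <- if (is.null(het)) rep(params$lambda, params$S) else het$lambda_i
  if (params$topology == "nearest_neighbor_1d") {
    P <- nrow(field)
    if (P == 1) return(field * 0)
    up <- field[c(2:P, 1), , drop = FALSE]
    dn <- field[c(P, 1:(P - 1)), , drop = FALSE]
    sweep(0.5 * (up + dn - 2 * field), 2, lam, `*`)
  } else {
    nbar <- colMeans(field)
    sweep(sweep(-field, 2, nbar, `+`), 2, lam, `*`) # lam * (nbar - N)
  }
}

#' Deterministic drift of the metacommunity dynamics
#'
#' Per-entry deterministic rate of change: logistic growth with interspecies
#' competition plus the dispersal flux. Two algebraically equivalent groupings
#' of the growth term are available: `"logistic"` writes it as
#' \eqn{r N (1 - (\alpha/K) \sum_{j \ne i} N_j - N/K)} and `"growth_factor"`
#' as \eqn{r N (g_{eff} - N/K)}; they agree to floating-point tolerance and the choice
#' only matters for inspection.
#'
#' @inheritParams effective_growth_factor
#' @param grouping `"logistic"` or `"growth_factor"` (see Details).
#' @return A `P x S` matrix of rates (per generation).
#' @export
deterministic_rates <- function(field, params, het = NULL,
                                grouping = c("growth_factor", "logistic")) {
  grouping <- match.arg(grouping)
  field <- check_field(field, params)
  K <- params$K
  comp <- competition_load(field, params, het)
  if (is.null(het)) {
    growth <- if (grouping == "growth_factor") {
      params$r * field * ((1 - comp / K) - field / K)
    } else {
      params$r * field * (1 - comp / K - field / K)
    }
  } else {
    growth <- if (grouping == "growth_factor") {
      geff <- effective_growth_factor(field, params, het)
      sweep(field * (geff - field / K), 2, het$r_i, `*`)
    } else {
      sweep(field * (1 - field / K), 2, het$r_i, `*`) -
        (params$r / K) * field * comp
    }
  }
  growth + dispersal_term(field, params, het)
}

check_field <- function(field, params) {
  field <- as.matrix(field)
  if (nrow(field) != params$P || ncol(field) != params$S)
    stop(sprintf("field must be %d x %d (patches x species)",
                 params$P, params$S), call. = FALSE)
  if (any(field < 0)) stop("abundances must be >= 0", call. = FALSE)
  field
}

#' Initial abundance field
#'
#' The standard initial condition: every entry at the carrying capacity `K`
#' with small random perturbations, implemented as independent Poisson(K)
#' draws (integer-valued, mean `K`, relative fluctuation `1/sqrt(K)`).
#'
#' @param params A [model_params()] object.
#' @return A `P x S` integer matrix.
#' @export
initial_condition <- function(params) {
  matrix(stats::rpois(params$P * params$S, params$K), params$P, params$S)
}

#' Summary observables of an abundance field
#'
#' @inheritParams effective_growth_factor
#' @return A one-row tibble with the global mean abundance, mean effective
#'   growth factor, number of extant species and mean local diversity
#'   (species with nonzero abundance per patch).
#' @export
field_observables <- function(field, params, het = NULL) {
  field <- check_field(field, params)
  geff <- effective_growth_factor(field, params, het)
  tibble::tibble(
    mean_abundance = mean(field),
    mean_geff = mean(geff),
    n_extant_species = sum(colSums(field) > 0),
    mean_local_diversity = mean(rowSums(field > 0))
  )
}

#' Per-species observables of an abundance field
#'
#' @inheritParams effective_growth_factor
#' @return A tibble with one row per species: patch-averaged abundance
#'   `species_mean`, patch-averaged effective growth factor `geff_species`,
#'   and whether the species is globally extinct (total abundance zero).
#' @export
species_observables <- function(field, params, het = NULL) {
  field <- check_field(field, params)
  geff <- effective_growth_factor(field, params, het)
  tibble::tibble(
    species = seq_len(params$S),
    species_mean = colMeans(field),
    geff_species = colMeans(geff),
    extinct = colSums(field) == 0
  )
}
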