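#' Simulate the stochastic metacommunity dynamics
#'
#' Integrates the metacommunity forward in time. Each generation is advanced
#' by Euler-forward substeps of length `dt` for the deterministic drift
#' (growth, competition, dispersal), after which every (patch, species)
#' abundance is redrawn from a Poisson distribution with the drifted value as
#' mean. The once-per-generation redraw implements demographic noise with
#' variance equal to the abundance per generation and keeps recorded states
#' integer-valued; the all-extinct configuration is absorbing, and once a
#' species' total abundance reaches zero it stays zero.
#'
#' Summary observables (mean abundance, mean effective growth factor, number
#' of extant species, mean local diversity) are recorded every `record_every`
#' generations, along with optional per-species traces and presence/absence
#' (occupancy) matrices for selected species.
#'
#' @param params A [model_params()] object.
#' @param het Optional [heterogeneous_params()] for species-specific rates.
#' @param t_max Duration in generations (> 0).
#' @param record_every Sampling interval in whole generations.
#' @param init Initial abundance field (`P x S` matrix) or `NULL` for the
#'   standard Poisson(K) initial condition.
#' @param noise If `FALSE`, the Poisson redraw is skipped and the dynamics are
#'   purely deterministic (diagnostic mode; abundances then need not be
#'   integers).
#' @param record_species Record per-species patch means and effective growth
#'   factors at every sample.
#' @param occupancy_species Integer indices of species whose presence/absence
#'   over (time, patch) should be stored.
#' @param seed Optional integer seed set before the initial condition is
#'   drawn, making the run reproducible.
#'
#' @return An object of class `"metacomm_sim"`: a list with `summary` (tibble
#'   of recorded observables), `species` (final-state per-species tibble),
#'   `final_field`, optional `species_mean` / `species_geff` trace matrices,
#'   `occupancy` (named list of time x patch logical matrices), and the full
#'   parameter record.
#' @examples
#' p <- model_params(lambda = 0.4, S = 2, P = 50)
#' sim <- simulate_metacommunity(p, t_max = 100, seed = 1)
#' sim$summary
#' @export
simulate_metacommunity <- function(params, het = NULL, t_max,
                                   record_every = 1, init = NULL,
                                   noise = TRUE, record_species = FALSE,
                                   occupancy_species = integer(0),
                                   seed = NULL) {
  stopifnot(inherits(params, "model_params"), t_max > 0)
  if (!is.null(het)) {
    stopifnot(inherits(het, "heterogeneous_params"))
    if (length(het$r_i) != params$S)
      stop("heterogeneous parameters do not match `params$S`", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  record_every <- as.integer(round(record_every))
  if (record_every < 1)
    stop("`record_every` must be >= 1 generation", call. = FALSE)
  n_gen <- as.integer(round(t_max))
  n_gen <- max(record_every, (n_gen %/% record_every) * record_every)
  if (is.null(init)) init <- initial_condition(params)
  init <- check_field(init, params)
  occupancy_species <- as.integer(occupancy_species)
  if (length(occupancy_species) &&
      (min(occupancy_species) < 1 || max(occupancy_species) > params$S))
    stop("`occupancy_species` out of range", call. = FALSE)

  res <- .sim_core(init,
                   params$r, params$K, params$alpha, params$lambda, params$dt,
                   ifelse(params$topology == "global", 1L, 0L),
                   FALSE, 1.0,
                   !is.null(het),
                   if (is.null(het)) numeric(0) else het$r_i,
                   if (is.null(het)) numeric(0) else het$lambda_i,
                   if (is.null(het)) matrix(0, 0, 0) else het$alpha_ij,
                   n_gen, record_every, noise,
                   record_species, occupancy_species)
  build_sim(res, params, het, record_every, occupancy_species, seed,
            single_g = NULL)
}

#' Simulate the decoupled single-species reference dynamics
#'
#' Integrates the single-species lattice dynamics in which the effective
#' growth factor is replaced by a fixed control parameter `g`:
#' `dN/dt = r N (g - N/K) + dispersal + demographic noise`. This is the
#' reference process whose absorbing-state transition (in the directed
#' percolation universality class) defines the critical growth factor `g_c`;
#' at `g = 1` it coincides with the `S = 1` metacommunity.
#'
#' @param g Fixed growth factor (dimensionless; values above/below `g_c`
#'   give survival/extinction).
#' @param r,K,lambda,P,dt,topology As in [model_params()].
#' @param record_occupancy If `TRUE` (default), the time x patch
#'   presence/absence matrix is stored for pattern analysis.
#' @inheritParams simulate_metacommunity
#' @return A `"metacomm_sim"` object (see [simulate_metacommunity()]); the
#'   occupancy matrix, if recorded, is `sim$occupancy[["1"]]`.
#' @examples
#' sim <- simulate_single_species(g = 0.95, lambda = 0.89, P = 100,
#'                                t_max = 200, seed = 1)
#' @export
simulate_single_species <- function(g, r = 0.3, K = 10, lambda = 0.89,
                                    P = 1000L, dt = 0.1,
                                    topology = "nearest_neighbor_1d",
                                    t_max = 1000, record_every = 1,
                                    init = NULL, noise = TRUE,
                                    record_occupancy = TRUE, seed = NULL) {
  params <- model_params(r = r, K = K, alpha = 0, lambda = lambda,
                         S = 1L, P = P, topology = topology, dt = dt)
  if (!is.null(seed)) set.seed(seed)
  record_every <- as.integer(round(record_every))
  n_gen <- as.integer(round(t_max))
  n_gen <- max(record_every, (n_gen %/% record_every) * record_every)
  if (is.null(init)) init <- initial_condition(params)
  init <- check_field(init, params)
  res <- .sim_core(init, r, K, 0, lambda, dt,
                   ifelse(topology == "global", 1L, 0L),
                   TRUE, g, FALSE, numeric(0), numeric(0), matrix(0, 0, 0),
                   n_gen, record_every, noise, FALSE,
                   if (record_occupancy) 1L else integer(0))
  build_sim(res, params, NULL, record_every,
            if (record_occupancy) 1L else integer(0), seed, single_g = g)
}

build_sim <- function(res, params, het, record_every, occupancy_species,
                      seed, single_g) {
  summary <- tibble::tibble(
    time = res$time,
    mean_abundance = res$mean_abundance,
    mean_geff = res$mean_geff,
    n_extant_species = as.integer(res$n_extant_species),
    mean_local_diversity = res$mean_local_diversity
  )
  final <- res$final_field
  species <- if (is.null(single_g)) {
    species_observables(final, params, het)
  } else {
    tibble::tibble(species = 1L, species_mean = mean(final),
                   geff_species = single_g, extinct = sum(final) == 0)
  }
  occ <- res$occupancy
  names(occ) <- as.character(occupancy_species)
  occ <- lapply(occ, function(m) {
    dimnames(m) <- NULL
    attr(m, "time") <- res$time
    attr(m, "dt_sample") <- record_every
    class(m) <- c("occupancy_matrix", class(m))
    m
  })
  structure(list(summary = summary, species = species, final_field = final,
                 species_mean = res$species_mean,
                 species_geff = res$species_geff,
                 occupancy = occ, params = params, het = het,
                 record_every = record_every, seed = seed,
                 single_g = single_g),
            class = "metacomm_sim")
}

#' @export
print.metacomm_sim <- function(x, ...) {
  p <- x$params
  n <- nrow(x$summary)
  cat(sprintf("<metacomm_sim> S = %d, P = %d, topology = %s%s\n",
              p$S, p$P, p$topology,
              if (!is.null(x$single_g)) sprintf(", fixed g = %g", x$single_g)
              else ""))
  cat(sprintf("  %d samples over %g generations; final mean abundance %.4g, %d extant species\n",
              n, max(x$summary$time), x$summary$mean_abundance[n],
              x$summary$n_extant_species[n]))
  invisible(x)
}

#' Presence/absence matrix of one species over time and space
#'
#' @param sim A `"metacomm_sim"` object with occupancy recorded for `species`.
#' @param species Species index.
#' @return A time x patch logical matrix (class `"occupancy_matrix"`), `TRUE`
#'   where the species is present; sampling times and interval are attached
#'   as attributes.
#' @export
occupancy <- function(sim, species = 1L) {
  stopifnot(inherits(sim, "metacomm_sim"))
  key <- as.character(as.integer(species))
  if (!key %in% names(sim$occupancy))
    stop(sprintf("occupancy was not recorded for species %s", key),
         call. = FALSE)
  sim$occupancy[[key]]
}

#' Tidy per-sample observables of a simulation
#'
#' @param x A `"metacomm_sim"` object.
#' @param ... Unused.
#' @return The summary tibble (one row per recorded sample).
#' @method tidy metacomm_sim
#' @export
tidy.metacomm_sim <- function(x, ...) x$summary

#' One-row summary of a simulation's final state
#'
#' @param x A `"metacomm_sim"` object.
#' @param ... Unused.
#' @return A one-row tibble: final time, final mean abundance and mean
#'   effective growth factor, extant species count, and whether the
#'   metacommunity is globally extinct.
#' @method glance metacomm_sim
#' @export
glance.metacomm_sim <- function(x, ...) {
  n <- nrow(x$summary)
  tibble::tibble(
    t_final = x$summary$time[n],
    mean_abundance = x$summary$mean_abundance[n],
    mean_geff = x$summary$mean_geff[n],
    n_extant_species = x$summary$n_extant_species[n],
    globally_extinct = x$summary$n_extant_species[n] == 0L
  )
}

#' Plot summary trajectories of a simulation
#'
#' @param object A `"metacomm_sim"` object.
#' @param ... Unused.
#' @return A ggplot of mean abundance and mean effective growth factor
#'   against time.
#' @method autoplot metacomm_sim
#' @export
autoplot.metacomm_sim <- function(object, ...) {
  df <- tidyr::pivot_longer(object$summary,
                            c("mean_abundance", "mean_geff"),
                            names_to = "observable")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (generations)", y = NULL)
}

#' Plot a spatiotemporal occupancy pattern
#'
#' @param object An `"occupancy_matrix"` (see [occupancy()]).
#' @param ... Unused.
#' @return A ggplot raster of presence (dark) and local extinction (white)
#'   over time (x) and patch (y).
#' @method autoplot occupancy_matrix
#' @export
autoplot.occupancy_matrix <- function(object, ...) {
  time <- attr(object, "time")
  df <- tibble::tibble(
    time = rep(time, times = ncol(object)),
    patch = rep(seq_len(ncol(object)) - 1L, each = nrow(object)),
    present = as.vector(object)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$patch,
                                   fill = .data$present)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "darkgreen",
                                          `FALSE` = "white"),
                               guide = "none") +
    ggplot2::labs(x = "time (generations)", y = "patch")
}
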