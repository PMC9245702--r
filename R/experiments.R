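#' Sweep the dispersal rate and classify survival
#'
#' Runs the metacommunity at each dispersal rate of a grid and classifies the
#' final state as surviving (any species extant) or globally extinct. The
#' smallest grid value with survival brackets the dispersal threshold; near
#' and below it all species die out, while well above it the mean population
#' size grows with the dispersal rate.
#'
#' @param lambdas Numeric vector of dispersal rates to scan.
#' @param params A [model_params()] object; its `lambda` entry is replaced by
#'   each grid value in turn.
#' @param t_max Duration of each run in generations.
#' @param seed Optional seed (one stream across the whole sweep).
#' @return A tibble with one row per grid point: `lambda`, final
#'   `mean_abundance`, `n_extant_species`, mean effective growth factor and
#'   `survived`.
#' @examples
#' \donttest{
#' p <- model_params(S = 1, P = 100)
#' sweep_lambda(c(0.005, 0.05), p, t_max = 500, seed = 1)
#' }
#' @export
sweep_lambda <- function(lambdas, params, t_max = 1e4, seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(lambdas, function(lam) {
    p <- params
    p$lambda <- lam
    sim <- simulate_metacommunity(p, t_max = t_max, record_every = t_max)
    g <- glance(sim)
    tibble::tibble(lambda = lam,
                   mean_abundance = g$mean_abundance,
                   n_extant_species = g$n_extant_species,
                   mean_geff = g$mean_geff,
                   survived = !g$globally_extinct)
  })
}

#' Smallest surviving dispersal rate of a sweep
#'
#' @param sweep A tibble from [sweep_lambda()].
#' @return The smallest `lambda` with `survived = TRUE` (`NA` if none).
#' @export
threshold_from_sweep <- function(sweep) {
  s <- sweep$lambda[sweep$survived]
  if (!length(s)) NA_real_ else min(s)
}

#' Experiment configuration
#'
#' Builds a validated configuration for [run_experiment()]: a subcommand, the
#' full model parameter set, heterogeneity standard deviations, duration,
#' sampling policy, seed and analysis options. Configurations round-trip
#' losslessly through YAML via [write_experiment_config()] /
#' [read_experiment_config()], and every run's output embeds the
#' configuration used.
#'
#' @param subcommand One of `"simulate"`, `"meanfield"`, `"dp"`, `"sweep"`.
#' @param params A [model_params()] object.
#' @param sigma_r,sigma_alpha,sigma_lambda Heterogeneity standard deviations
#'   (0 for the homogeneous model).
#' @param t_max Duration in generations.
#' @param record_every Sampling interval in generations.
#' @param seed Integer seed.
#' @param lambdas Grid for the `"sweep"` subcommand.
#' @param g Fixed growth factor for the `"dp"` subcommand (or `NULL` to
#'   estimate the critical value first).
#' @param burn_in Generations discarded before pattern statistics
#'   (`"dp"` subcommand).
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(subcommand = c("simulate", "meanfield", "dp",
                                             "sweep"),
                              params = model_params(), sigma_r = 0,
                              sigma_alpha = 0, sigma_lambda = 0,
                              t_max = 1000, record_every = 1, seed = 1,
                              lambdas = NULL, g = NULL, burn_in = 0) {
  subcommand <- match.arg(subcommand)
  stopifnot(inherits(params, "model_params"))
  if (t_max <= 0) stop("`t_max` must be > 0", call. = FALSE)
  if (any(c(sigma_r, sigma_alpha, sigma_lambda) < 0))
    stop("sigmas must be >= 0", call. = FALSE)
  structure(list(subcommand = subcommand, params = params,
                 sigma_r = sigma_r, sigma_alpha = sigma_alpha,
                 sigma_lambda = sigma_lambda, t_max = t_max,
                 record_every = record_every, seed = as.integer(seed),
                 lambdas = lambdas, g = g, burn_in = burn_in),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %s (seed %d, t_max %g)\n",
              x$subcommand, x$seed, x$t_max))
  print(x$params)
  invisible(x)
}

#' @rdname experiment_config
#' @param config An `"experiment_config"` object.
#' @param path File path for the YAML representation.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  x <- unclass(config)
  x$params <- unclass(x$params)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  p <- x$params
  experiment_config(subcommand = x$subcommand,
                    params = model_params(r = p$r, K = p$K, alpha = p$alpha,
                                          lambda = p$lambda, S = p$S, P = p$P,
                                          topology = p$topology, dt = p$dt),
                    sigma_r = x$sigma_r, sigma_alpha = x$sigma_alpha,
                    sigma_lambda = x$sigma_lambda, t_max = x$t_max,
                    record_every = x$record_every, seed = x$seed,
                    lambdas = unlist(x$lambdas), g = x$g,
                    burn_in = x$burn_in %||% 0)
}

#' Run a configured experiment and write its outputs
#'
#' Dispatches on the configuration's subcommand: `"simulate"` integrates the
#' (possibly heterogeneous) metacommunity and writes summary and per-species
#' tables; `"meanfield"` solves the self-consistency condition and writes the
#' solution and the normalized density on a grid; `"dp"` runs the
#' single-species reference dynamics near criticality and writes cluster
#' statistics and power-law fits; `"sweep"` scans dispersal rates. Every
#' output directory contains `config.yaml` (the exact configuration) and
#' `metadata.json` (parameters, seed, versions, wall-clock).
#'
#' @param config An [experiment_config()] object.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the result object (simulation, solution, sweep tibble
#'   or fit list).
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  p <- config$params
  set.seed(config$seed)
  het <- if (config$sigma_r > 0 || config$sigma_alpha > 0 ||
             config$sigma_lambda > 0)
    draw_heterogeneous_params(p, config$sigma_r, config$sigma_alpha,
                              config$sigma_lambda)
  else NULL

  result <- switch(
    config$subcommand,
    simulate = {
      sim <- simulate_metacommunity(p, het = het, t_max = config$t_max,
                                    record_every = config$record_every,
                                    record_species = TRUE)
      write_simulation(sim, out_dir)
      sim
    },
    meanfield = {
      sol <- solve_self_consistent(p$r, p$K, p$lambda, p$alpha, p$S)
      utils::write.csv(glance(sol), file.path(out_dir, "solution.csv"),
                       row.names = FALSE)
      if (sol$nontrivial) {
        Ns <- seq(p$K / 400, 1.3 * p$K, length.out = 400)
        dens <- abundance_density(Ns, sol$nbar, p$r, p$K, p$lambda, p$alpha,
                                  p$S)
        utils::write.csv(tibble::tibble(N = Ns, density = dens),
                         file.path(out_dir, "density.csv"), row.names = FALSE)
      }
      sol
    },
    dp = {
      g <- config$g %||% {
        est <- estimate_gc(p$r, p$K, p$lambda, P = p$P, dt = p$dt,
                           t_max = min(config$t_max, 1e4))
        est$upper + 0.01
      }
      sim <- simulate_single_species(g = g, r = p$r, K = p$K,
                                     lambda = p$lambda, P = p$P, dt = p$dt,
                                     t_max = config$t_max,
                                     record_every = config$record_every)
      occ <- occupancy(sim)
      occ <- occ[attr(occ, "time") > config$burn_in, , drop = FALSE]
      lens <- extinction_run_lengths(occ)
      taus <- recolonization_times(occ, dt_sample = config$record_every)
      utils::write.csv(lens, file.path(out_dir, "extinction_lengths.csv"),
                       row.names = FALSE)
      utils::write.csv(taus, file.path(out_dir, "recolonization_times.csv"),
                       row.names = FALSE)
      fits <- list(g = g)
      for (nm in c("length", "tau")) {
        xs <- if (nm == "length") lens$length[!lens$censored]
              else taus$tau[!taus$censored]
        fit <- tryCatch(
          fit_power_law(xs, x_max = straight_fit_range(xs)),
          error = function(e) NULL)
        if (!is.null(fit)) fits[[nm]] <- as.list(glance(fit))
      }
      jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                           auto_unbox = TRUE, digits = NA)
      fits
    },
    sweep = {
      lambdas <- config$lambdas %||%
        stop("`lambdas` required for the sweep subcommand", call. = FALSE)
      sw <- sweep_lambda(lambdas, p, t_max = config$t_max)
      utils::write.csv(sw, file.path(out_dir, "sweep.csv"), row.names = FALSE)
      sw
    })

  write_experiment_config(config, file.path(out_dir, "config.yaml"))
  meta <- list(parameters = unclass(p),
               sigma = list(r = config$sigma_r, alpha = config$sigma_alpha,
                            lambda = config$sigma_lambda),
               seed = config$seed, subcommand = config$subcommand,
               wall_clock_sec = as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")),
               r_version = R.version.string,
               package_version = as.character(utils::packageVersion("metacrit")))
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(result)
}

#' Re-run a headline experiment at reduced scale
#'
#' Reproduces the package's headline analyses at their standard parameters
#' (growth rate 0.3, carrying capacity 10, competition strength 0.1),
#' scaled down by `scale` in patch
#' number, species number and duration so they finish at desk scale:
#' \describe{
#'   \item{`"threshold"`}{dispersal sweep showing the survival threshold
#'     (zero plateau, then increasing mean abundance).}
#'   \item{`"patterns"`}{near-critical single-species run with occupancy
#'     pattern and power-law fits of extinction lengths and times.}
#'   \item{`"meanfield"`}{self-consistent abundance distribution against a
#'     global-dispersal simulation histogram.}
#'   \item{`"heterogeneous"`}{species-specific interaction and dispersal
#'     rates; effective growth factors of surviving versus extinct species
#'     relative to the critical growth factor.}
#' }
#'
#' @param tag Which experiment to run (see Details).
#' @param scale Reduction factor in (0, 1]; 1 is the full standard size.
#' @param out_dir Optional directory to write tables into.
#' @param seed Integer seed.
#' @return A list of result tibbles/objects (content depends on `tag`).
#' @export
reproduce_figure <- function(tag = c("threshold", "patterns", "meanfield",
                                     "heterogeneous"),
                             scale = 0.2, out_dir = NULL, seed = 1) {
  tag <- match.arg(tag)
  stopifnot(scale > 0, scale <= 1)
  set.seed(seed)
  sc <- function(x, lo) max(lo, round(x * scale))
  out <- switch(
    tag,
    threshold = {
      p <- model_params(lambda = 0.01, S = 5, P = sc(500, 50))
      lams <- c(0.001, 0.002, 0.005, 0.01, 0.02, 0.04, 0.08, 0.15, 0.3, 0.6)
      sw <- sweep_lambda(lams, p, t_max = sc(1e4, 1000))
      list(sweep = sw, lambda_c_bracket = threshold_from_sweep(sw))
    },
    patterns = {
      est <- estimate_gc(lambda = 0.89, P = sc(1000, 100),
                         t_max = sc(1e4, 1000), n_rep = max(4, sc(20, 4)))
      sim <- simulate_single_species(g = est$upper + 0.01, lambda = 0.89,
                                     P = sc(1000, 100), t_max = sc(5e4, 2000))
      occ <- occupancy(sim)
      occ <- occ[attr(occ, "time") > sc(1e4, 500), , drop = FALSE]
      lens <- extinction_run_lengths(occ)
      taus <- recolonization_times(occ)
      list(gc = est, occupancy = occ,
           lengths = lens, times = taus,
           length_fit = tryCatch(fit_power_law(lens$length[!lens$censored]),
                                 error = function(e) NULL),
           time_fit = tryCatch(fit_power_law(taus$tau[!taus$censored]),
                               error = function(e) NULL))
    },
    meanfield = {
      p <- model_params(lambda = 0.1, S = 5, P = sc(500, 100),
                        topology = "global")
      sol <- solve_self_consistent(p$r, p$K, p$lambda, p$alpha, p$S)
      sim <- simulate_metacommunity(p, t_max = sc(5000, 1000),
                                    record_every = 10)
      list(solution = sol, simulation = sim,
           abundances = as.vector(sim$final_field))
    },
    heterogeneous = {
      S <- sc(300, 30); P <- sc(2000, 200)
      p <- model_params(lambda = 0.4, S = S, P = P)
      het <- draw_heterogeneous_params(p, sigma_alpha = 0.5 / S,
                                       sigma_lambda = 0.03)
      sim <- simulate_metacommunity(p, het = het, t_max = sc(2e4, 2000),
                                    record_every = 10, record_species = TRUE)
      est <- estimate_gc(lambda = 0.4, P = min(P, 200), t_max = sc(1e4, 1000),
                         n_rep = max(4, sc(20, 4)))
      list(species = sim$species, gc = est, simulation = sim)
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      if (tibble::is_tibble(out[[nm]]))
        utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
    }
  }
  out
}
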