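#' Write a simulation to a directory of plain-text files
#'
#' A trajectory is stored as a self-describing bundle: `summary.csv` (one row
#' per recorded sample), `species.csv` (final-state per-species table),
#' `final_field.csv` (patch x species abundances), one `occupancy_<i>.csv`
#' per recorded species (0/1, one row per sample), and `metadata.json`
#' holding the full parameter set, any heterogeneous draws, the seed and the
#' sampling policy.
#'
#' @param sim A `"metacomm_sim"` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "metacomm_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$species, file.path(dir, "species.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sim$final_field),
                   file.path(dir, "final_field.csv"), row.names = FALSE)
  for (nm in names(sim$occupancy)) {
    m <- sim$occupancy[[nm]]
    utils::write.csv(as.data.frame(m * 1L),
                     file.path(dir, paste0("occupancy_", nm, ".csv")),
                     row.names = FALSE)
  }
  p <- sim$params
  meta <- list(parameters = unclass(p),
               heterogeneous = if (!is.null(sim$het)) {
                 h <- sim$het
                 list(r_i = h$r_i, lambda_i = h$lambda_i,
                      alpha_ij = as.vector(h$alpha_ij),
                      sigma_r = h$sigma_r, sigma_alpha = h$sigma_alpha,
                      sigma_lambda = h$sigma_lambda)
               },
               single_g = sim$single_g,
               record_every = sim$record_every,
               seed = sim$seed,
               occupancy_species = as.integer(names(sim$occupancy)))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a simulation bundle written by [write_simulation()]
#'
#' @param dir Directory containing the bundle.
#' @return A `"metacomm_sim"` object. Trace matrices that were not stored
#'   (per-species time series) are absent; everything else round-trips.
#' @export
read_simulation <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  p <- meta$parameters
  params <- model_params(r = p$r, K = p$K, alpha = p$alpha,
                         lambda = p$lambda, S = p$S, P = p$P,
                         topology = p$topology, dt = p$dt)
  het <- if (!is.null(meta$heterogeneous) &&
             length(meta$heterogeneous)) {
    h <- meta$heterogeneous
    heterogeneous_params(h$r_i, h$lambda_i,
                         matrix(h$alpha_ij, params$S, params$S),
                         sigma_r = h$sigma_r, sigma_alpha = h$sigma_alpha,
                         sigma_lambda = h$sigma_lambda)
  }
  summary <- tibble::as_tibble(utils::read.csv(file.path(dir, "summary.csv")))
  species <- tibble::as_tibble(utils::read.csv(file.path(dir, "species.csv")))
  final <- as.matrix(utils::read.csv(file.path(dir, "final_field.csv")))
  dimnames(final) <- NULL
  occ <- list()
  for (i in meta$occupancy_species) {
    m <- as.matrix(utils::read.csv(
      file.path(dir, paste0("occupancy_", i, ".csv")))) > 0
    dimnames(m) <- NULL
    attr(m, "time") <- summary$time
    attr(m, "dt_sample") <- meta$record_every
    class(m) <- c("occupancy_matrix", class(m))
    occ[[as.character(i)]] <- m
  }
  structure(list(summary = summary, species = species, final_field = final,
                 species_mean = NULL, species_geff = NULL,
                 occupancy = occ, params = params, het = het,
                 record_every = meta$record_every, seed = meta$seed,
                 single_g = meta$single_g),
            class = "metacomm_sim")
}
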