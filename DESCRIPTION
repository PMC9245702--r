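Package: metacrit
Title: Stochastic Metacommunity Dynamics at the Edge of Extinction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and theory for species-rich metacommunities of weakly
    competing species with self-consistent dispersal. Provides a stochastic
    Lotka-Volterra lattice simulator with demographic (Poisson) noise,
    nearest-neighbour and global dispersal, a self-consistent mean-field
    theory for the species abundance distribution and its dispersal
    threshold, and directed-percolation pattern analysis: estimation of the
    critical growth factor, extinction-cluster length and recolonization-time
    statistics, and discrete power-law fits of their distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
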