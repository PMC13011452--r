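Package: microsojourn
Title: Sojourn Trajectory Macroecology for Microbiome Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize excursions of microbial taxa away from their
    steady-state abundance ("sojourn trajectories") in dense 16S rRNA time
    series, and to interpret them with the stochastic logistic model (SLM) of
    growth. Provides sampling-aware maximum-likelihood inference of each
    taxon's mean relative abundance and coefficient of variation under a
    gamma-Poisson (negative binomial) read-count likelihood, extraction of
    sojourn, residence and return run-length statistics from log-rescaled
    abundance series, two temporal-structure-free null models (stationary
    gamma draws and time-label permutation) with a divergence statistic,
    simulation-based SLM predictions of the sojourn-time distribution, of
    height-versus-CV scaling and of mean sojourn times, and a synthetic-data
    generator that simulates SLM communities observed through finite-depth
    multinomial sequencing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
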