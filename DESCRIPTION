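Package: foxscr
Title: Spatial Capture-Recapture Density Estimation from Non-Invasive
    Genetic Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimates carnivore density from non-invasive genetic sampling
    (NGS) with maximum-likelihood spatial capture-recapture (SCR).
    Provides replicate-consensus microsatellite genotype calling with a
    quality index and threshold filter, detector-grid and buffered
    state-space construction with covariate extraction, a multi-session
    Poisson-count SCR likelihood with a half-normal encounter model and
    covariates on density, baseline encounter rate and space-use scale,
    AIC model selection over a structured candidate set, and derived
    outputs: expected and realized density surfaces, regional abundance,
    and sex-specific home-range areas.  A synthetic-data generator
    emulates the grid-based sampling design so the full pipeline can be
    exercised and validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
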