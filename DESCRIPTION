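Package: wellforecast
Title: Spatiotemporal Modelling and Forecasting of Chemotherapy Response in Cell Culture Wells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model, calibrate and forecast the spatiotemporal growth
    and chemotherapy response of in-vitro cancer cell colonies observed by
    time-resolved microscopy. Implements a two-phenotype (surviving/damaged)
    reaction-diffusion model solved by an explicit finite-difference scheme on
    pixelated cell-density maps, bounded nonlinear least-squares calibration
    with residual-bootstrap uncertainty, variance-based global sensitivity
    analysis, and a leave-one-out weekly data assimilation-prediction pipeline
    that blends population-level priors with replicate-specific estimates via
    concordance-weighted parameter transfer. A synthetic-experiment generator
    emulates dose-dependent well dynamics so the full pipeline can be
    exercised and tested without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
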