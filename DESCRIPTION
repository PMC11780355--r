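Package: whiskpop
Title: Cerebellar Population Dynamics During Whisking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of Neuropixels population recordings from the lateral
    cerebellar cortex of head-fixed mice during voluntary whisking, and of
    chemogenetic perturbations of glycinergic (GlyT2-positive) interneurons.
    Provides whisker kinematics from tracked landmarks (azimuthal angle,
    Hilbert phase/amplitude/set point, bout segmentation), single-unit tuning
    curves with shuffle controls, spline smoothing, k-means taxonomy and
    entropy/KL statistics, trial-aligned population PCA with neural-behavioral
    cross-correlation and set-point decoding, a hierarchical Bayesian
    inverse-Gamma model of normalized population spike counts with posterior
    contrasts, and movement-onset timing and coupling analyses. A synthetic
    data generator emulating bout-structured whisking, tuned Poisson
    populations and the count-panel generative model makes every stage
    testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    car,
    coda,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    signal,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
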