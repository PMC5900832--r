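Package: hdpolymarker
Title: Imaging Polymarker Modelling of Proximity to Onset in Premanifest
    Huntington's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multimodal imaging
    "polymarker" studies of premanifest Huntington's disease. Generates
    synthetic cohorts with genetic clock scores (disease burden, CAP,
    Langbehn estimated years to diagnosis), network time courses and
    structural features carrying proximity-to-onset gradients; estimates
    pairwise resting-state network coupling by a dual general linear model;
    screens edges and forms hypo-/hyper-connectivity composites; provides
    the univariate statistical battery (mixed-design ANOVA with generalized
    eta-squared, Tukey post-hocs, Spearman and partial Spearman with
    confidence intervals, Steiger z, Mann-Whitney with Hodges-Lehmann
    estimates, Lilliefors-style normality check); and evaluates
    imbalance-weighted linear support-vector classifiers with leave-one-out
    F1, permutation nulls, hyperplane-distance conversion prediction and
    cross-cohort validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
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
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
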