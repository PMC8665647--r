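Package: ontokine
Title: Plasma Cytokine and Chemokine Ontogeny Analysis by Trajectory Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for longitudinal plasma cytokine/chemokine
    panels measured on bead-based multiplex immunoassay plates: standard-curve
    quantification (4PL/5PL/exponential fits with detection and quantification
    limits, censoring imputation and bead-count filtering), empirical-Bayes
    plate batch correction with bridge-sample QC, near-zero-variance analyte
    filtering, paired nonparametric ontogeny statistics with Holm adjustment,
    PCA and covariate association models, and dynamic-time-warping
    bootstrap-consensus clustering of mean standardized trajectories with
    silhouette-based selection of the number of clusters. Ships a synthetic
    neonatal cohort generator that plants five kinetic trajectory classes so
    every stage of the pipeline is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    caret,
    cluster,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
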