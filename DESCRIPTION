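Package: adaptr
Title: Dynamic Adaptations in Parameter Trajectories for Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates time-dependent parameter trajectories of metabolic
    ordinary-differential-equation models from longitudinal metabolite data
    (ADAPT: Analysis of Dynamic Adaptations in Parameter Trajectories).
    Measurement uncertainty is propagated by a Monte Carlo ensemble of cubic
    smoothing splines; longitudinal gene-expression data refine the estimated
    trajectories through two regularization terms that reward temporal
    correlation between parameters and their coupled genes and damp parameter
    fluctuations where gene expression is static. Includes ensemble analyses
    (regularization-constant scans, correlation-based solution grouping,
    variance reduction), decomposition of a metabolite pool's net rate into
    additive and subtractive flux routes with fractional contributions and
    peak timing, and a synthetic-data module with known ground truth for
    benchmarking every stage.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
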