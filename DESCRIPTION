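Package: robustps
Title: Robust Population Stratification Correction for Genome-Wide
    Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Outlier-robust correction for population stratification in
    case-control genome-wide association studies.  Subject outliers are
    detected with projection-pursuit robust principal component analysis
    (GRID and CR algorithms, score/orthogonal distance diagnostics) or
    with resampling by half means; population structure is then modelled
    by classical principal components with Tracy-Widom component
    selection and k-medoids clustering with Gap-statistic model
    selection; per-SNP association is tested by covariate-adjusted
    logistic regression.  Includes discrete and admixed population
    simulators with configurable subject-outlier injection and a
    benchmark harness estimating empirical false and true positive
    rates of six stratification-correction strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
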