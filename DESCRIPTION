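Package: yieldtrends
Title: Century-Scale Crop Yield Trend, Stagnation and Variability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing long annual panels of sub-national crop
    yields: quality filtering of outlying yield records, local linear trend
    estimation with a dynamic linear model (Kalman filter/smoother with
    maximum-likelihood variance estimation), equivalence-test scoring of
    recent growth rates to detect yield stagnation, inter-annual variability
    analytics (decadal coefficients of variation, Taylor power-law scaling,
    residual skewness, cross-crop residual correlations), era-wise UPGMA
    clustering of departmental mean yields with Calinski-Harabasz model
    selection, correlation of yield series with fertilizer inputs, and a
    synthetic panel generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
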