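Package: fertimap
Title: Small-Area Fertility Rates, Deprivation Indices and Bayesian
    Spatial Smoothing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small-area analysis of urban fertility inequalities:
    construction of a MEDEA-style socioeconomic deprivation index from five
    census indicators, stratified crude fertility rates per 1000 women,
    Besag-York-Mollie (BYM) hierarchical Bayesian smoothing of tract-level
    rates via Metropolis-within-Gibbs MCMC with an intrinsic CAR spatial
    prior, and a three-period ecological Poisson regression of fertility on
    deprivation with period interactions, summarised as relative risks
    comparing the 95th to the 5th percentile of deprivation. Includes a
    synthetic-city generator with known ground truth so every stage is
    testable without registry microdata, plus readers and writers for GAL
    spatial-weights files and GeoJSON choropleths.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
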