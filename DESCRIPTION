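Package: pwshazard
Title: Hazard Assessment of Arsenic in Private Water Supplies from
    Stratified Log-Normal Exposure Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for geology-stratified hazard assessment of arsenic in
    private (non-mains) drinking-water supplies.  Fits per-stratum
    log-normal exposure models from dwelling-level concentration records,
    selects normalising transformations on Tukey's ladder of powers with
    the D'Agostino-Pearson omnibus normality test, compares strata with
    robust Levene and Kruskal-Wallis tests, converts fitted models to
    exposure-category probabilities and regulatory-limit exceedance, ranks
    strata on a four-level hazard scale, and predicts dwelling counts per
    exposure band.  Includes a synthetic-data generator for left-censored
    log-normal survey data and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
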