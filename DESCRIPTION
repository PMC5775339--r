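Package: dietshift
Title: Diet Indices, Regime Shifts and Ordination for Seabird Diet Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing long-term seabird diet-sample time series as
    indicators of marine ecosystem change. Computes the four standard diet
    composition indices (frequency of occurrence, average wet weight, average
    meal mass, average mass percentage) from per-bird regurgitate records,
    detects regime shifts in annual series by change-point analysis with
    small-sample information-criterion model selection, compares prey groups
    within years by Monte-Carlo two-sample permutation tests, builds sea-ice
    and volume-weighted temperature indices and correlates them with diet
    (raw and detrended, Fisher-z confidence intervals), ordinates years by
    Bray-Curtis dissimilarity with Ward clustering and non-metric
    multidimensional scaling, reconstructs forage-fish lengths and age
    classes from otolith measurements, and generates synthetic sample tables
    with a two-regime structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
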