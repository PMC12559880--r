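Package: reciproSOC
Title: Depth-Resolved Soil Organic Carbon Change from Land-Use Change by
    Data-Driven Reciprocal Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates equilibrium soil organic carbon (SOC) stock change
    following land-use change between cropland, grassland and forest, resolved
    by depth down to 90 cm. Implements depth harmonization of fixed-increment
    soil inventories (1-cm downscaling and weighted re-aggregation under exact
    stock conservation), equilibrium and organic-soil screening, a stacked
    ensemble of random forest, gradient-boosted trees and support-vector
    regression trained under repeated nested spatial cross-validation with
    random hyperparameter search, dissimilarity-index screening of the area of
    applicability, counterfactual prediction with bootstrap confidence
    intervals, and a post-hoc driver analysis via permutation importance and
    accumulated local effects. Includes a synthetic soil-inventory generator
    with known ground-truth counterfactual stocks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    xgboost,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
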