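Package: heatrisk
Title: Heat Health Risk Assessment and CA-Markov Prediction on Gridded Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for composite heat health risk assessment on
    1-km indicator rasters. Normalizes hazard, social-vulnerability and exposure
    indicators, derives indicator weights from principal component analysis
    (with KMO and Bartlett sphericity diagnostics), combines them into a
    multiplicative hazard x vulnerability x exposure risk surface, classifies it
    into five levels by exact Jenks natural breaks, accounts for class areas,
    transitions and dominant-factor subzones, and projects future risk maps with
    a from-scratch CA-Markov simulator validated by Cohen's kappa. A seeded
    synthetic-data generator produces spatially structured multi-year indicator
    stacks so the whole workflow runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
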