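Package: rangeshift
Title: Ensemble Species Distribution Modelling of Climate-Driven Range Shifts
Version: 0.1.0
Authors@R: person("rangeshift", "developers", email = "dev@rangeshift.invalid", role = c("aut", "cre"))
Description: A tested, reusable pipeline for projecting climate-driven range
    shifts of a species from occurrence records and monthly climate grids:
    occurrence cleaning and spatial/environmental thinning, bioclimatic and
    terrain predictor derivation with collinearity screening, tuned
    presence-background suitability models (a MaxEnt-style penalized
    logistic learner, random forests and boosted trees) under spatial-block
    cross-validation, multi-metric evaluation (AUC, AUC-PR, TSS, Sorensen,
    Cohen's kappa, Brier score, Continuous Boyce Index), gated multi-method
    ensembles with clamping and uncertainty masks, and range-change,
    centroid-shift and altitude-shift statistics. A synthetic-data module
    generates climate, elevation and occurrence inputs with known ground
    truth so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    deldir,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
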