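Package: rangecast
Title: Ensemble Species Distribution Models of Range Contraction Under
    Warming and AMOC-Weakening Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for assessing species range contraction and
    assemblage-level species loss under a high-warming control scenario and
    freshwater-hosing (AMOC-weakening) scenarios.  Generates synthetic
    climate worlds and virtual species with known Gaussian niches so every
    stage is testable without external data; computes bioclimatic variables
    (bio1, bio5, bio6, bio12, bio15) from monthly climatologies with delta
    bias correction; fits MaxEnt-style penalized logistic, boosted-tree and
    classification-tree suitability models on realm-background
    pseudoabsences with repeated 70/30 subsampling; binarizes suitability
    under MTP, 10thTP, ESS and MSS threshold criteria; and derives per
    species proportional range loss under full- and no-dispersal
    assumptions, stacked richness grids and per-cell species diversity
    deficits.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    rpart,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
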