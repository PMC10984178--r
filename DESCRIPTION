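Package: corridorscape
Title: Ensemble Habitat Suitability and Circuit-Theory Connectivity for
    Large Mammal Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling habitat suitability and movement
    connectivity of large, conflict-prone mammals across fragmented
    landscapes. Prepares presence records (conflict-point relocation into
    forest, spatial rarefaction, pseudo-absence sampling, collinearity
    screening), fits a six-algorithm ensemble of species distribution
    models (GLM, GAM, boosted trees, MARS-style hinge regression, random
    forest and a penalized-logistic maximum-entropy equivalent) with
    AUC-weighted averaging, converts suitability to a movement resistance
    surface, and analyses connectivity between core habitat nodes with
    least-cost paths, cost-weighted corridors, circuit-theory effective
    resistance, current density (pinch points) and current-flow
    centrality. Includes a synthetic landscape generator with known
    ground truth for end-to-end validation, and the published core-node
    and movement-pathway tables of an Asian elephant study as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    mgcv,
    randomForest,
    xgboost,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
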