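Package: ppievolve
Title: Protein-Protein Interaction Prediction and Ranking with
    Pareto-Based Evolutionary Model Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds curated protein-protein interaction (PPI) datasets from
    PSI-MITAB-style interaction tables, characterizes protein pairs with a
    fixed 61-feature panel (GO-term similarity, orthology and database
    flags, domain-domain interactions, co-localization, co-expression and
    physicochemical sequence descriptors), and trains classification and
    binding-strength regression ensembles with a multi-objective
    Pareto-based evolutionary algorithm that jointly selects features,
    estimator kind (support vector machine or random forest) and
    hyperparameters under stratified cross-validation. Fitted Pareto
    fronts drive interactome screening: candidate pairs are classified,
    positive pairs receive a predicted binding free energy, and
    interactions are ranked by the mean of classification probability and
    scaled affinity. A synthetic-world generator with planted interaction
    signal makes the whole stack testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
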