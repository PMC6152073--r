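Package: dtirvm
Title: Drug-Target Interaction Prediction from PSSM Bi-Gram Features
    with Relevance Vector Machines
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts drug-target interactions from protein sequence
    profiles. Parses PSI-BLAST position-specific scoring matrices (PSSMs),
    converts each protein into a 400-dimensional bi-gram transition
    feature vector, reduces feature matrices by principal component
    analysis, and classifies drug-target pairs with a sparse Bayesian
    relevance vector machine trained by evidence maximization. Includes
    balanced negative sampling on bipartite interaction networks,
    stratified k-fold cross-validation with accuracy, sensitivity,
    precision, Matthews correlation and ROC/AUC reporting, seeded
    synthetic-data generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    Biostrings,
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
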