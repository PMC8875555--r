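Package: dualscreen
Title: Ligand-Based Virtual Screening for Dual-Target Inhibitor Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for discovering dual-target enzyme
    inhibitors by ligand-based virtual screening. Curates potency-annotated
    molecule libraries into representative active sets, generates
    property-matched topologically dissimilar decoys, trains and
    cross-validates fingerprint-based binary classifiers selected by the
    Matthews correlation coefficient, screens chemical libraries with
    nearest-active annotation, compares Tanimoto similarity distributions
    between ligand sets, and fits enzyme-inhibition dose-response curves
    (IC50 with Cheng-Prusoff conversion to Ki and Monte-Carlo uncertainty)
    and differential scanning fluorimetry melt curves (Boltzmann Tm with
    3-SD thermal-shift significance calls). Ships a synthetic benchmark
    generator so every stage is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    ChemmineR,
    ChemmineOB,
    methods,
    stats,
    utils,
    graphics,
    glmnet,
    randomForest,
    xgboost,
    rpart,
    class,
    minpack.lm,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
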