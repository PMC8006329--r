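Package: RecoveryBBN
Title: Bayesian Belief Network Prognostic Modeling of Functional Recovery
    After Snakebite Envenoming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links clinical features and a 35-analyte multiplex
    cytokine/chemokine panel to functional recovery from pit viper
    envenoming. Implements the Patient-Specific Functional Scale area
    under the patient curve (AUPC) outcome with median dichotomization,
    missingness filtering, discrete Bayesian belief network structure
    learning scored by minimum description length, leave-one-out
    first-degree-associate model selection, exact posterior inference,
    and leave-one-out cross-validated ROC/AUC evaluation. Ships a seeded
    synthetic cohort generator with a planted dependency structure so the
    whole pipeline is testable without patient-level data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
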