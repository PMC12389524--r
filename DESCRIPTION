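Package: qsarmix
Title: Mixed-Kernel Support Vector Regression QSAR Modeling with CLPSO
    Hyperparameter Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative structure-activity relationship (QSAR)
    regression of inhibitor potency (lg IC50) from molecular descriptors.
    Implements epsilon-insensitive support vector regression over a mixed
    kernel (convex combination of trigonometric, polynomial and linear
    kernels), comprehensive-learning particle swarm optimization (CLPSO) of
    hyperparameters with cross-validated fitness, gradient-boosted and
    random-forest tree ensembles with split-gain feature importance and
    correlation-filtered descriptor selection, a linear-QSAR path with
    descriptor pre-filtering and forward selection, internal and external
    validation statistics (Q2 LOO, Q2 k-fold, CCC, QF1^2, QF2^2,
    y-randomization) and a leverage-based applicability domain with Williams
    classification. Ships a transcribed reference table of measured and
    predicted lg(IC50) for 92 EGFR L858R/T790M/C797S inhibitors and a
    synthetic-data generator so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
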