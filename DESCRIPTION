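Package: ansid
Title: Task Identification from Autonomic Indices of Heart Rate
    Variability and Electrodermal Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for identifying the
    cognitive task a subject is performing from autonomic nervous system
    reactions. Extracts four spectral indices of heart rate variability
    (HRVLF, HRVHF and their normalized forms) from ECG and four
    electrodermal indices (SCL, NS.SCRs, EDASymp, TVSymp) from skin
    conductance, then classifies task condition (baseline, psychomotor
    vigilance, auditory n-back, visual ship search) with seven
    classifiers under leave-one-subject-out cross-validation, including
    exhaustive feature-subset search and temporal-generalization
    evaluation across repeated trials. A synthetic-cohort generator
    (integral pulse frequency modulation for beat times, Bateman-kernel
    Poisson process for skin conductance responses) provides labelled
    recordings with known ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    pracma,
    glmnet,
    Matrix,
    MASS,
    class,
    e1071,
    rpart,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
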