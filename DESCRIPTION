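Package: gaitbv
Title: Pedigree BLUP and Machine-Learning Breeding Values for Gait Visual Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete pipeline for the genetic evaluation of visually scored
    horse gaits: pedigree handling (inbreeding, numerator relationship matrix,
    truncation), a quantitative-genetics simulator with Mendelian sampling,
    fixed-effect adjustment by ordinary least squares, multi-trait animal-model
    BLUP with EM-REML variance components (exact trace terms via sparse
    selected inversion of the mixed-model equations), machine-learning breeding
    value predictors (multilayer perceptron, epsilon-SVR with a Gaussian
    kernel, random forest regression) trained on adjusted phenotypes,
    technician dummies and relationship-matrix eigenvectors, and validation by
    the linear-regression (LR) method.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    randomForest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
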