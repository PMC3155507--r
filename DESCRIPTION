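Package: betaturn
Title: Beta-Turn Prediction with Shape Strings and a Two-Layer SVM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts beta-turns in protein chains from position-specific
    scoring matrices, predicted three-state secondary structure and
    homology-transferred shape strings (eight-state phi/psi torsion
    alphabets). Shape strings are assigned by e-value-ranked greedy
    transfer from aligned database sequences. Sliding 8-residue windows
    are encoded as logistic-scaled PSSM plus one-hot tracks and
    classified by a stacked model: two cluster-specific RBF support
    vector machines act as probability generators whose estimates feed a
    second-layer SVM. Includes geometric turn labelling from C-alpha
    traces, the Q_total/Q_predicted/Q_observed/MCC/ROC evaluation
    protocol under seven-fold cross-validation, and deterministic
    synthetic-data generators for every input format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
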