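Package: cpprofiler
Title: Comparative Physicochemical Profiling of Membrane Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interpretable sequence-based feature engineering and substrate
    prediction for single-span membrane proteins. Implements Comparative
    Physicochemical Profiling (CPP), which compares two sets of proteins by
    exhaustively combining sequence parts (transmembrane and juxtamembrane
    regions), residue-selection rules (segments, patterns, periodic
    patterns), and min-max normalized amino-acid property scales, then
    filters the resulting feature space by test-set dispersion, mean
    difference, a rank-based adjusted AUC, and redundancy. Also provides
    deterministic positive-unlabeled learning (dPULearn) for selecting
    reliable negatives via principal-component distances, a Monte Carlo
    ensemble training harness over ten classifier families, tree-SHAP
    per-feature attribution with fuzzy labeling for unlabeled proteins,
    per-residue importance profiles, and a synthetic data generator with
    plantable physicochemical signatures for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr,
    stringr,
    Biostrings,
    rpart,
    randomForest,
    ranger,
    xgboost,
    glmnet,
    e1071,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
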