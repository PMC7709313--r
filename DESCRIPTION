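Package: fvtlda
Title: Predicting lncRNA-Disease Associations from Tripartite
    miRNA-Centred Association Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers candidate long non-coding RNA (lncRNA) to disease
    associations by combining indirect evidence (restart random walks over
    miRNA similarity networks built from a Gaussian interaction-profile
    kernel and from MeSH-based disease semantic similarity) with direct
    evidence (known lncRNA-disease links smoothed into graded association
    probabilities through similarity-weighted voting). Per-pair feature
    vectors are mapped to association scores with either multiple linear
    regression or a small feed-forward neural network. Includes
    leave-one-out and k-fold cross-validation with rank-based ROC/AUC,
    case-study candidate ranking with a contrast score, and a synthetic
    tripartite data generator with planted block structure for fully
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
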