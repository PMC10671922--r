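Package: cawfuse
Title: Consensus-Adaptive Weighting for Ensemble Fusion of Binary Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-level fusion of probabilistic binary classifiers by
    consensus-adaptive weighting (CAW): each base model receives a fusion
    weight proportional to its validation F2 score (V1) or to a power of it
    (V2), with the sharpening exponent selected by exhaustive grid search
    over cross-validation folds. Includes soft (probability-averaging)
    fusion, a majority-vote baseline, a stratified cross-validation
    evaluation harness, class-imbalance utilities (majority-class
    undersampling, balanced batch construction, augmentation-count
    planning), and a seeded generator of correlated synthetic classifier
    scores for end-to-end testing without trained models.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
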