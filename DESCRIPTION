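Package: msep
Title: Margin and Sensitivity Based Ensemble Pruning for Electronic-Nose
    Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selective-ensemble toolkit for breath volatolomics and other
    gas-sensor-array classification problems. Provides a synthetic
    electronic-nose data generator (multichannel transient response curves
    and direct classifier vote matrices), a gated-recurrent sequence
    autoencoder for unsupervised feature extraction from multichannel time
    series, bagged CART ensemble training, voting-margin computation, and
    four ordering or greedy ensemble-pruning measures: the margin and
    sensitivity based measure (MSM, with its margin-only MEP ablation), the
    unsupervised margin based measure (UMEP), the margin and diversity
    based measure (MDM), and the simultaneous diversity and accuracy
    measure (SDAcc). An evaluation harness runs repeated stratified
    train/prune/test splits, reports accuracy, sensitivity, specificity
    and AUC, and applies a rank-scoring rule for comparing models.
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
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
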