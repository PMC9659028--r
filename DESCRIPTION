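Package: slidemets
Title: Detection and Evaluation of Lymph Node Metastases in Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying breast-cancer lymph-node metastasis detection
    on whole-slide images at desk scale. Generates synthetic slide cohorts with
    planted micro- and macro-metastases and model-like tumor-probability
    heatmaps; builds study manifests with isolated-tumor-cell exclusion and
    stratified splits; implements a valid-padding densely connected
    convolutional classifier with fully convolutional slide inference; patch
    sampling, stain-style augmentation and retraining strategies including
    hard negative mining; heatmap post-processing into detection regions with
    automatic TNM slide labels; and slide-level AUC plus lesion-level FROC
    evaluation with bootstrap confidence intervals and permutation tests.
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
    igraph,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
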