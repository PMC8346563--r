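Package: exuscan
Title: Two-Stage Screening and Localisation of Hard Exudates in Retinal Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-stage pipeline for localising hard exudates in
    colour fundus photographs: full images are padded and tiled into 224x224
    patches, a linear support-vector-machine gate trained on fixed-length
    patch embeddings discards exudate-free patches, and the retained patches
    are passed to an object-detection backend whose boxes are mapped back to
    image coordinates. Includes a seeded synthetic fundus generator with
    per-pixel ground truth, patch augmentation (shifting, mirroring,
    contrast jitter with black-background preservation), multi-expert mask
    fusion, stratified cross-validation folds, and the matching evaluation
    protocol: filled-box pixel-overlap matching at the exudate level,
    maximum-patch-score decisions at the image level, sensitivity /
    specificity / PPV / F1 / FPR / FNR metrics, ROC-AUC, and fold
    aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
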