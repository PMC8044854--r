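Package: gadcell
Title: Classification of GAD67-Positive Interneurons from Multichannel Fluorescence Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether single cortical neurons are GABAergic
    (GAD67-positive) from multichannel confocal micrographs. Provides a seeded
    synthetic micrograph generator with ground truth, morphological preprocessing
    (per-plane intensity normalization, erosion-dilation splitting of fused
    regions of interest, area filtering, tight cropping), a variable-input-size
    fully convolutional classifier trained with checkpointing, a PCA plus
    RBF-SVM baseline, and a cross-validated channel-ablation harness reporting
    per-class precision, recall, F1 and the class-size-weighted F1 with paired
    t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
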