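Package: aanet
Title: Aggregation-and-Attention Network for Brain Tumor MRI Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An encoder-decoder convolutional network for multi-modal brain
    MRI tumor segmentation that aggregates multi-scale context and attends to
    spatial and channel structure. Provides enhanced down-sampling encoder
    blocks with deep supervision, multi-scale dilated-convolution skip
    connections, a dual-attention (positional + channel) fusion bottleneck,
    residual up-sampling decoder layers, the composite deep-supervision
    BCE+Dice loss, BraTS-style NIfTI preprocessing (z-score normalization,
    center crop, axial slicing, modality stacking), nested tumor-region
    evaluation metrics (Dice, precision, sensitivity, Hausdorff distance over
    whole/core/enhancing tumor), a synthetic multi-modal phantom generator so
    the whole pipeline is testable without external data, and training with
    Adam and early stopping. All network layers and reverse-mode gradients
    are implemented in the package (RcppArmadillo kernels plus an R tape).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
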