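Package: sinusct
Title: Volumetric Lund-Mackay Scoring of Sinus CT with Semi-Supervised Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated three-dimensional volumetric scoring of paranasal sinus
    computed tomography for chronic rhinosinusitis. Provides a seeded generator
    of synthetic sinus-CT phantoms with exact ground truth, a compact
    encoder-decoder semantic segmentation network built from depthwise-separable
    convolutions, squeeze-and-excitation channel gating (Mish activation),
    residual connections and atrous spatial pyramid pooling, a semi-supervised
    self-training loop with confidence-filtered pseudo-labels and a
    Gaussian-mixture partition of per-sample losses, per-region volumetry with
    air/disease partitioning, the continuous volume-based modified Lund-Mackay
    score (VMLMs) alongside an automated traditional Lund-Mackay score (TLMs),
    and the accompanying evaluation statistics (Dice/MIoU/pixel accuracy,
    ROC with Youden cut-points, symptom-responder rules, cohort regression).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
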