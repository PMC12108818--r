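Package: whanet
Title: Wavelet-Attention Hybrid Network for Optic Disc Edema Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained implementation of WHA-Net, a low-complexity hybrid
    convolutional/transformer classifier for fundus photographs that separates
    normal optic discs, optic disc edema (ODE) and pseudopapilledema (PPE).
    Provides the Haar wavelet convolution block (fixed orthonormal 2x2 filter
    bank, recursive two-level decomposition, per-subband depthwise convolution
    and exact inverse-transform aggregation), scSE hybrid channel/spatial
    attention, inverted residual and hybrid-attention inverted residual blocks,
    linear-complexity agent attention with MobileViT-style unfold/fold token
    processing, analytic parameter and multiply-accumulate budgets, a seeded
    synthetic fundus image generator with class-conditional phenotypes, the
    offline/online augmentation stack, an optic disc localizer/cropper, an
    AdamW training loop with cosine learning-rate annealing, one-vs-rest
    classification metrics, confidence-threshold flagging and Grad-CAM
    explanations. All layers carry explicit forward and backward passes so the
    network trains on CPU without external deep-learning frameworks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tibble,
    jsonlite,
    yaml,
    png,
    EBImage,
    ggplot2,
    rlang
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    dplyr,
    tidyr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
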