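Package: cowreid
Title: Multi-Branch Deep Metric Learning for Cattle Face Re-Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Open-set re-identification of individual Holstein cattle from face
    images. Implements the Global-and-Part Network (GPN), a three-branch
    embedding model over a convolutional backbone with last-stride-1
    modification, and its spatial-transformer extension (GPN-ST) in which four
    constrained attention modules replace uniform stripe partition. Includes
    the full training objective (batch-hard triplet loss, label-smoothed
    cross-entropy, affine-constraint losses), identity-balanced PK batch
    sampling, training-time augmentation, cosine-similarity ranking evaluation
    (CMC Rank-k, mAP, capped gallery sweeps), a deterministic synthetic
    cattle-face fixture generator, and a command-line interface. The network
    engine (reverse-mode automatic differentiation with compiled convolution,
    pooling and bilinear-sampling kernels) is self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
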