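Package: numerogen
Title: Numerosity-Conditioned Autoregressive Image Generation with Self-Attention
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Synthesizes dot-array numerosity stimuli (uniform dots, non-uniform
    dots with constant expected cumulative area, smoothed squares), fits an
    encoder-only self-attention network that models images pixel-by-pixel as a
    product of conditional categorical densities given a learned numerosity
    embedding, and probes the learned embedding space through out-of-distribution
    generation (interpolated, extrapolated and PCA-reduced conditioning seeds).
    Includes the dataset-specific counting heuristics (area-ratio counter and a
    compact convolutional classifier) and the analysis layer that turns sample
    batches into numerosity histograms, scalar-variability summaries and the
    principal-component view of the embedding space.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
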