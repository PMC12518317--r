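Package: cnatnet
Title: Lightweight Convolution-Attention Networks for Safflower Filament Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements CNATNet, a lightweight hybrid convolution-attention
    image classifier for coarse-to-fine quality grading of safflower
    (Carthamus tinctorius) filaments, together with the building blocks it is
    assembled from: the cascaded split-and-concatenate C2S2 module, the
    attention-enhanced cross-stage fusion AnC2f module with sigmoid-gated
    attention blocks, and the depthwise-separable DWClassify head. Provides
    analytic parameter and FLOP accounting with a brute-force enumeration
    oracle, an ablation-variant factory with n/s/m scale presets, a
    procedural synthetic filament-scene generator with manifests and
    stratified splits, and a seeded training and evaluation pipeline. All
    layers (convolution, batch normalization, SiLU, linear) carry
    hand-written backpropagation over Rcpp im2col kernels, so the package is
    self-contained and runs on a plain CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
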