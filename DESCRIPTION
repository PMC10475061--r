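Package: svpnet
Title: Detection of Spontaneous Retinal Venous Pulsations in Fundus Videos
Version: 0.1.0
Authors@R:
    person("SVP", "Maintainers", email = "maintainers@svpnet.example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for autonomous classification of
    spontaneous retinal venous pulsations (SVPs) in fundus videos. An
    attention-gated recurrent-residual U-Net with depthwise-separable
    convolutions localizes the optic disc in each frame; a cropper extracts a
    disc-centered 30-frame grayscale clip; and a family of spatio-temporal
    classifiers (3D Inception, 3D Dense-ResNet, 3D ResNet, LRCN, ConvLSTM)
    labels the pulsation as present or absent. All network layers, including
    a reverse-mode automatic-differentiation engine with compiled
    convolution kernels, are implemented in the package. A synthetic fundus
    phantom generator with analytic ground truth makes the whole pipeline
    trainable and testable at desk scale without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
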