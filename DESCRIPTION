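Package: ldctscn
Title: Stacked Competitive Networks for Low-Dose CT Noise Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end toolkit for studying convolutional denoising of
    low-dose computed tomography (CT) images on fully synthetic data. The
    package simulates paired normal-dose/low-dose CT slices from ellipse
    attenuation phantoms via Siddon ray-driven fan-beam projection, Poisson
    photon statistics at a controllable blank-scan flux, and fan-beam
    filtered back-projection. On such pairs it trains stacked competitive
    networks: fully convolutional networks whose layers compute convolutions
    at several kernel scales, apply a rectifier to each, and combine them by
    an element-wise maximum. Training follows a greedy layer-wise
    pretraining plus supervised fine-tuning regimen with an Adam-then-SGD
    schedule, and results are scored with PSNR, RMSE and SSIM over full
    images or regions of interest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
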