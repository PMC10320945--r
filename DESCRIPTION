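Package: DoseFluence
Title: Simultaneous 3D Dose and Fluence-Map Prediction for Nine-Beam IMRT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for simultaneous prediction of volumetric dose
    distributions and per-beam fluence maps for nine-beam head-and-neck
    IMRT plans. Implements a shared-encoder convolutional network with a
    dose decoder and a fluence decoder ending in a differentiable
    beam's-eye-view geometric projection head, ground-truth fluence
    reconstruction from MLC control-point sequences, synthetic digital
    phantoms with a forward dose engine and reference-plan optimizer,
    masked dual-loss training with geometric augmentation, sliding-window
    whole-volume inference with logarithmic overlap blending, and a full
    evaluation suite (masked MAE, SSIM, gamma pass rates, DVH and clinical
    dose indices, paired nonparametric tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Matrix, Rcpp, jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
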