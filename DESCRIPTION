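Package: tawssnet
Title: Point-Cloud U-Net Surrogates for Time-Averaged Wall Shear Stress in
    Coronary Bifurcations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates parametric idealized left-coronary bifurcation
    geometries (LM/LAD/LCx) as fixed-size structured surface point clouds,
    labels them with a pulsatile, morphology-dependent wall shear stress
    surrogate built on Carreau-Yasuda rheology, Poiseuille wall shear and
    Murray flow splitting, canonically orders the clouds by principal
    component projection, and trains a compact convolutional U-Net that
    regresses per-point time-averaged wall shear stress (TAWSS) from point
    coordinates. Includes the MRE and range-normalized NAME error metrics,
    reproducible train/validation/test split manifests, PLY/CSV point-cloud
    input and output, and an ordering-ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    lhs,
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
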