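Package: senseIO
Title: Task-Based Image-Quality Bounds for Accelerated Multi-Coil MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates upper bounds on signal-detection performance from raw
    under-sampled multi-coil MRI k-space data and compares them with observer
    performance on reconstructed images.  Simulates a stylized multi-coil
    SENSE (sensitivity encoding) acquisition with Cartesian undersampling and
    complex Gaussian noise, generates stochastic object ensembles (lumpy
    backgrounds and stylized brain phantoms with a tissue mask for signal
    placement), and evaluates binary signal-detection tasks with analytic
    likelihood-ratio ideal observers, Hotelling observers, and a depth-grown
    convolutional-network approximation of the ideal observer.  Reconstruction
    baselines (root sum-of-squares, conjugate-gradient SENSE, and a small
    learned reconstructor) together with RMSE/SSIM metrics support comparing
    task-based bounds against traditional image-quality measures across
    acceleration factors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    RNifti
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
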