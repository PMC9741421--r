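Package: dotbench
Title: Frequency-Domain Diffuse Optical Tomography Workbench
Version: 0.1.0
Authors@R: person("DOT", "Workbench Maintainers", email = "maintainers@dotbench.org", role = c("aut", "cre"))
Description: An end-to-end workbench for frequency-domain diffuse optical
    tomography (DOT) of circular, breast-like phantoms. Provides a structured
    finite-element forward solver for the photon diffusion equation on disk
    meshes, a synthetic phantom and measurement-set generator for a 16-fiber
    ring-scanning probe, a Tikhonov-regularized (Levenberg-Marquardt style)
    iterative inverse solver with adjoint Jacobians, a sensor-to-image
    branching convolutional neural network (domain transform, background
    predictor and U-net refinement) trained with a weighted coefficient loss,
    and contrast-size-detail (CSD) resolution metrics for scoring
    reconstructed absorption and reduced-scattering images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
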