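Package: hemomesh
Title: Template-Deforming Hybrid Image/Graph Network for Vascular Meshes and Hemodynamics
Version: 0.1.0
Authors@R: person("Hemomesh", "Developers", email = "hemomesh@example.org", role = c("aut", "cre"))
Description: Converts a 3D grayscale cardiac image volume plus a scalar inlet
    velocity into a patient-specific tetrahedral volume mesh of a bifurcating
    vessel with per-node pressure and velocity, by deforming a point-correspondent
    template mesh with a hybrid image-encoder / graph-convolutional network.
    Includes the differentiable mesh-quality and flow losses, a seeded synthetic
    Y-vessel generator with analytic Poiseuille flow as a CFD stand-in,
    point-correspondence utilities, and segmentation/flow evaluation metrics
    (Dice, ASSD, Hausdorff, normalized absolute error, Bland-Altman).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    xml2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
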