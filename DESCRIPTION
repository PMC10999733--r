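Package: fibertwist
Title: Fiber Orientation, Curvature and Twist Analysis for Tissues Grown on
    Rotationally Symmetric Scaffolds
Version: 0.1.0
Authors@R: person("fibertwist", "developers", role = c("aut", "cre"),
    email = "fibertwist@example.org")
Description: Quantifies twisted-plywood-like fiber architectures in tissues
    grown on negative-Gaussian-curvature scaffolds (capillary bridges and
    their pore negatives). Provides constant-mean-curvature (Delaunay)
    profile solvers and curvature evaluation for surfaces of revolution,
    structure-tensor fiber-orientation estimation on maximum intensity
    projections, lifting of image-plane angles onto the 3D surface, normal
    curvature along the fiber direction via Euler's theorem, chirality and
    depth-resolved twist classification, actin-collagen co-alignment and
    signal-offset measures, and histogram-peak aggregation statistics. A
    synthetic renderer generates helical multilayer image stacks with known
    ground truth so the full pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
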