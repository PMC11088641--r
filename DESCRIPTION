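Package: femurbc
Title: Boundary-Condition Benchmarking for Isolated-Femur Finite-Element Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale finite-element pipeline for studying how constraining
    boundary conditions affect simulated femoral mechanics during gait. Provides
    a parametric synthetic femur generator (linear tetrahedral mesh with a
    pseudo-CT greyscale field, anatomical landmarks and muscle attachment
    patches), greyscale-to-density-to-modulus material mapping with binned
    material sets, a femur deformation toolbox for anteversion and neck-shaft
    pathologies, a stance-phase gait load fixture, a linear elastic tetrahedral
    solver with couplings, springs, sliders and inertia relief, six constraining
    boundary-condition formulations, and outcome measures (femoral head
    deflection, peak von Mises stress, cortical strain paths) with R-squared and
    normalised-RMSE comparison against the inertia-relief benchmark.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
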