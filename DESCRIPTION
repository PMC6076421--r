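Package: patchtv
Title: Combined Nonlocal-Patch and Total-Variation Reconstruction for
    Limited-View Photoacoustic Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative image reconstruction for two-dimensional photoacoustic
    tomography with straight-line (limited-view) detector scanning. Implements
    the patch-TV solver, which augments total-variation minimization with an
    adaptive nonlocal patch penalty built from steering-kernel (structure
    tensor) similarity weights, solved by variable splitting with
    Barzilai-Borwein step sizes. Ships the circular-arc forward projector,
    analytic ellipse phantoms (Shepp-Logan and a FORBILD-style head), noise
    injection, baseline solvers (gradient-descent TV, patch-only
    regularization, backprojection), image-quality metrics (PSNR, relative
    distance), and a config-driven experiment runner with ggplot2 output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    ggplot2,
    tibble,
    generics,
    methods,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    dplyr,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Config/testthat/start-first: phantoms, grid, forward, nonlocal, solver-ops,
    reconstruction, metrics, experiments
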