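Package: anisoblock
Title: Conduction Block at Abrupt Fiber-Orientation Changes in Human Ventricular Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monodomain reaction-diffusion simulator for human ventricular
    tissue built on the ten Tusscher-Panfilov 2006 (TP06) epicardial ionic
    model, together with the analysis machinery needed to study conduction
    block at a straight border between regions of orthogonal fiber
    orientation. Provides single-cell equilibration and pacing, 1D cable and
    2D sheet integration with half-node flux discretisation and Neumann
    boundaries, anisotropic conductivity maps parameterised by the anisotropy
    ratio, activation and APD90 detectors, restitution curves, conduction
    classification (1:1, n:m, full block), bisection searches for the
    critical anisotropy ratio and critical pacing period/frequency, a closed
    form for the critical-period curve T(AR) with least-squares fitting, and
    2D reentry induction with phase-singularity tracking. Includes fast toy
    excitable-medium and passive-diffusion fixtures for testing the protocol
    machinery without the cost of the full ionic model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    minpack.lm,
    yaml,
    generics,
    digest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
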