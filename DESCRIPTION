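Package: atfm
Title: Astigmatic Traction Force Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for astigmatic traction force microscopy
    (aTFM): single-frame 3D localization of fiducial beads against a
    cubic-spline point-spread-function model by maximum-likelihood
    estimation, trajectory linking with drift correction and median
    filtering, interpolation of bead displacements onto regular grids, and
    conversion of gel-surface displacements into shear and normal stresses
    with an elastic half-space Green's-function solver. Includes the
    Hertzian sphere-indentation force calibration, Cramer-Rao bound and
    Monte-Carlo uncertainty estimation, a TIRF-geometry feasibility check,
    and a synthetic-data generator with known ground truth for every
    pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    interp,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
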