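Package: tendonswe
Title: Freehand 3D Shear Wave Elastography Analysis of the Patellar Tendon
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for volumetric shear wave
    elastography (SWE) of the patellar tendon. Provides a digital tendon
    phantom with known regional shear wave velocity (SWV), simulation of
    pose-tracked freehand 2D SWE sweeps, weighted-average compounding of
    2D frames into 3D voxel volumes, landmark-based partitioning of the
    tendon into proximal, mid-portion and distal regions, a cohort
    simulator with a linear generative model for regional SWV, and the
    statistical inference layer used in regional tendon studies:
    independent-samples t tests, ordinary least squares with exhaustive
    best-subset selection under leave-one-out (PRESS) or adjusted R-squared
    criteria, and between-group tests on regional SWV deltas.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
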