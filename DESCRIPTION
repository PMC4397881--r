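Package: hipsim
Title: CT-Based Dynamic Simulation of Hip Range of Motion and
    Femoroacetabular Impingement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates clinically defined hip motions (flexion, abduction,
    internal rotation at fixed flexion) on triangulated femur and pelvis bone
    surfaces, detects bony impingement by mesh collision queries with a capped
    corrective translation of the femoral head, registers range-of-motion
    endpoints, localizes the impinging area on a head-neck clock face, and
    estimates the bone resection that dissolves the impingement.  Includes ISB
    anatomical coordinate frames, sphere fitting of the hip rotation center,
    fiducial point-set registration, a parametric hip phantom with an analytic
    range-of-motion oracle, synthetic CT voxelization with iso-surface
    segmentation, and a native-versus-cam comparison layer with limitation
    detection at a configurable threshold and descriptive error statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tidyr,
    optparse,
    yaml
Config/testthat/edition: 3
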