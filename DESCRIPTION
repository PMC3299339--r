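Package: orbcal
Title: CBCT Orbital Implant Density Calibration and Longitudinal Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating porous orbital implants on cone beam CT
    (CBCT). CBCT intensity scales are not routinely water-calibrated, so the
    package maps per-scan "HU-like" values onto a water-calibrated MSCT
    reference scale with a two-point affine correction anchored on the
    contralateral corpus vitreum (water-like) and the dedicated orbital
    volume maximum (dense bone). It ships the 30-patient study table this
    analysis reproduces, voxel-volume region statistics, three-point and
    least-squares sphere fitting for implant diameter estimation,
    within/beyond factory-diameter classification, ordinary least squares
    trends of implant density against implant lifespan, and digital orbital
    phantom plus synthetic cohort generators with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
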