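Package: msmcalib
Title: Automatic Multi-Camera Extrinsic Calibration from Projected Multi-Scale Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: External (extrinsic) calibration of multi-camera systems from
    multi-scale fiducial markers projected onto a planar floor, targeted at
    3D surgical scene reconstruction rigs with strongly differing zoom levels
    and limited overlapping fields of view. Provides projective geometry
    primitives (robust homography estimation and decomposition, PnP,
    multi-view triangulation, Sim(3) alignment), a multi-scale marker model
    with projection schedules and a raster renderer, a square-fiducial
    detector with scale fusion, an incremental calibration pipeline with
    sparse bundle adjustment and an optional floor-coplanarity constraint,
    a synthetic rig simulator with moving-board gold-standard baselines, and
    pose-accuracy evaluation tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
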