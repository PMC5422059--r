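Package: branchnav
Title: Smartphone Sensor Fusion for Branch-Scan Video Control and Tree
    Georeferencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale implementation of a two-mode smartphone sensor-fusion
    workflow for field plant phenotyping in densely planted coffee. Navigation
    mode georeferences individual trees by GPS-seeded inertial dead reckoning:
    static periods are detected from a windowed local-maxima envelope of the
    inertial signal magnitude against a dynamic threshold, velocity is
    integrated with zero-velocity updates, per-segment drift is removed with a
    straight-line compensation, and calibrated displacements are rotated into
    Gauss-Kruger plane coordinates from a single GPS seed. Acquisition-control
    mode detects the start and end of the slow scan of a handset along a
    branch from gyroscope angular velocity, trims the companion video to the
    movement period, and selects sharp frames by circular region-of-interest
    edge-energy indexes (Sobel, Laplacian, Canny) on the red channel. A
    synthetic-data module generates walking traces, branch-scan traces and
    branch-like images with ground truth so the full pipeline runs without
    field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
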