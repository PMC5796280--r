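Package: thermonest
Title: Thermographic Nest-Occupancy Sensing for Laying Hens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A machine-vision "nest-usage sensor" for laying-hen monitoring built
    on grayscale thermographic frames of a nest interior. Estimates the floor
    (background) temperature from the histogram mode, binarizes the frame at a
    Background Color Threshold (floor temperature plus a Celsius shift), filters
    small particles, counts colored pixels, flags multiple nest occupation
    against a pixel-count threshold, and counts hens by rotated normalized
    cross-correlation template matching with elliptical (body) or triangular
    (head) templates. Includes the sensitivity-based threshold calibration
    procedure, sensitivity/specificity metrics, the RFID/egg/occupancy event
    state machine producing laying-hen records with egg-to-hen assignment, and
    seeded synthetic scene and event-stream generators for testing without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
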