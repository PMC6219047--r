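Package: tipvision
Title: Image-Based Pipette Volume Monitoring for Point-of-Care Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Camera-based quality control for the pump-driven pipette of
    point-of-care testing (POCT) instruments. Segments the red reagent
    column inside a translucent conical tip from a fixed-camera frame
    (luminance/pure-red colour difference, median filtering, fixed-threshold
    binarisation), measures the vertical support length of the binary
    projection (the "volume length"), calibrates the cube of that length
    against commanded pump steps by ordinary least squares, and flags pump
    malfunction when the step estimate recovered from an image deviates from
    the commanded steps beyond a configurable bound. Includes a parametric
    synthetic-scene generator with per-pixel ground truth for end-to-end
    validation without instrument hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
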