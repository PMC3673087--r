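Package: agrocam
Title: Camera Arrangement and Illumination Control for Crop and Weed Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for engineering the accuracy of tractor-mounted camera
    sensors used in precision agriculture. Models the pinhole projection of a
    ground region of interest into pixel coordinates to relate camera pitch,
    mounting height and target distance to achievable pixel resolution;
    implements a multiplicative exposure-time feedback controller driven by a
    white reference panel, radial lens-vignetting correction, greenness
    segmentation through a fuzzy-clustering global threshold, and segmentation
    scoring with the percentage-of-correct-classification index. A synthetic
    field-scene renderer (crop rows, weed patches, soil, orange reference
    cardboard, colour panel) with a linear sensor model provides ground-truth
    imagery so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    EBImage,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
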