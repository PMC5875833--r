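Package: focalspot
Title: Phantomless EPID Measurement of Linac Beam Focal-Spot Offset
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures the lateral offset of a medical linear accelerator's
    x-ray focal spot from the collimator rotation axis using only portal
    images (EPID) of jaw-defined and MLC-defined square fields acquired at
    collimator angles 90 and 270 degrees. The differing source-to-collimator
    distances of the jaws and the MLC make a focal-spot misalignment visible
    as a separation between the two field-centroid pairs at the detector
    plane, which a projection-geometry factor converts to a physical offset.
    Includes the half-blocked-field ionization-chamber cross-check, a
    forward simulator of portal images with known ground truth, DICOM RT
    Image and raw TIFF+YAML I/O, reproducibility statistics, and a
    command-line front-end for routine quality-assurance use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
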