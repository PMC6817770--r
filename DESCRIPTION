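Package: vesselmorph
Title: Morphometric Discrimination of Cerebral Arterioles and Venules from
    Cross-Section Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures segmented transverse cross-sections of small cerebral
    blood vessels (background/lumen/wall label masks with a microns-per-pixel
    calibration) and classifies each vessel as an arteriole or a venule from
    its lumen-to-wall area ratio, the criterion that separates the two vessel
    classes where the traditional lumen-diameter to wall-thickness ratio does
    not. Includes a calibrated synthetic cross-section generator with exact
    analytic ground truth for validating every estimator, lossless mask I/O
    with JSON sidecar metadata, a from-scratch Mann-Whitney U test (exact
    small-sample enumeration and tie-corrected normal approximation), and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
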