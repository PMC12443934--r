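Package: phantomqa
Title: Quality Assurance Analysis for a Low-Field MRI Phantom
Version: 0.1.0
Authors@R:
    person("phantomqa", "developers", email = "phantomqa@example.org",
           role = c("aut", "cre"))
Description: Tools for automated image-quality assessment of a 3D-printed,
    vial-based MRI phantom imaged on low-field (64 mT) systems. Provides a
    parametric digital model of the phantom, a spin-echo magnitude-image
    simulator with Rician noise and injectable geometric distortion,
    automated circular vial detection by thresholding and Hough/least-squares
    circle fitting, and the three quality measurands computed from phantom
    scans: one-dimensional geometric distortion via inter-vial distances,
    signal-to-noise ratio, and contrast-to-noise ratio. Images are read and
    written as NIfTI-1 or 16-bit PNG; reports as JSON or CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
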