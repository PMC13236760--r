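Package: freckletrace
Title: Quantification of Punctate Phosphatidylserine Externalization in
    TIRF Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and quantification of submicron, punctate
    phosphatidylserine-positive spots ("freckles") that appear in total
    internal reflection fluorescence (TIRF) time-lapse recordings of cells
    exposed to pulsed electric fields. Provides automated spot detection
    with per-cell intensity statistics, Gaussian line-scan fitting of spot
    profiles, bead-calibrated point-spread-function estimation, and a
    sphere-in-evanescent-field optical model that converts measured spot
    widths into physical vesicle diameters by quadrature deblurring.
    Includes frame-to-frame mobility classification, object-based
    two-channel colocalization, delta-F/F fluorescence traces, and a
    seeded forward simulator that renders TIRF-like image stacks with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    stats,
    utils,
    tiff
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
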