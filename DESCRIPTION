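Package: wsprsim
Title: Wavelength-Modulated Surface Plasmon Resonance Imaging Simulation
    and Adaptive Resonance-Wavelength Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and signal processing for multi-LED
    wavelength-modulated surface plasmon resonance imaging (WSPRi).
    Implements a Kretschmann-configuration transfer-matrix reflectance
    model for dispersive multilayers, an adaptive second-order fitting
    (ASF) resonance-wavelength tracker with overlapping LED bands and
    trigger-band switching, calibration and figure-of-merit analytics
    (sensitivity, refractive-index resolution, limit of detection,
    dynamic range), and a synthetic multi-wavelength image-stack
    generator for six-channel flow-cell scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
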