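Package: beamloop
Title: Automated Crystal Loop Centering and Unattended Data Collection on a Virtual Beamline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale re-implementation of the optical and diffraction-based
    sample-centering stack used for unattended macromolecular crystallography
    data collection. Provides computer-vision loop-tip detection and flat-face
    centering (sinusoidal projected-area fit), raster grid-scan aggregation
    with thresholded best-spot selection, a resumable per-sample automation
    state machine with a file-backed journal, sample-spreadsheet validation,
    and HTML run reports. All algorithms run against a built-in deterministic
    virtual beamline (parametric loop renderer plus simulated diffraction spot
    fields), so the full pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
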