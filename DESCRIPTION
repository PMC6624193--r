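Package: larvascape
Title: Proprioceptor Tracking and Ratiometric Calcium Analysis for
    Volumetric Movies of Crawling Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-channel (calcium-sensitive green,
    static red) volumetric fluorescence movies of crawling and exploring
    Drosophila larvae. Provides deskewing of oblique light-sheet stacks,
    3D soma tracking on the static red channel, ratiometric dR/R0 signal
    extraction with lowest-decile baselining, contraction-event detection
    with FWHM time-normalization and phase statistics, one-tailed paired
    activation-lag tests, and a planar two-bar kinematic model that
    decomposes exploration behavior into turning and head-retraction
    metrics. Includes a ground-truthed synthetic movie generator for
    validating every stage of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    rhdf5
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
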