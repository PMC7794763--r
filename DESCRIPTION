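Package: ergkit
Title: Scotopic Electroretinogram Feature Extraction, Simulation and Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing dark-adapted flash electroretinogram (ERG)
    recordings: trial averaging, pretrial baseline estimation, isolation of
    oscillatory potentials with a zero-phase Butterworth high-pass filter,
    a-wave and b-wave amplitude and implicit-time measurement, oscillatory
    potential peak detection, and eye selection.  Includes a synthetic
    scotopic ERG generator with analytically known ground truth for
    validating the extraction pipeline, a factorial ANOVA layer with
    Bonferroni post-hoc tests that also accepts printed mean/SEM/n summary
    tables, and quantification helpers for dual-luciferase reporter assays,
    relative qPCR expression, and standard-curve absorbance measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
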