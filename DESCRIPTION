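Package: sesisuppress
Title: Ion Suppression in Secondary Electrospray Ionization Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative machinery for studying gas-phase ion suppression in
    secondary electrospray ionization (SESI) mass spectrometry. Implements a
    Henry's-law evaporation-chamber gas-standard calculator, a seeded synthetic
    SESI-MS data generator (pulsed analyte delivery, competitive gas-phase
    suppression ordered by gas-phase basicity, humidity-dependent sensitivity,
    SIM-window scan scheduling, mzML output), an mzML signal-extraction
    pipeline (average spectrum, peak picking with a height filter, peak bounds
    at a height fraction, SIM-window stitching, per-scan integration), exact
    least-squares change-point segmentation of pulsed time traces, and
    dose-response suppression metrics (normalized curves, trend
    classification, fractional loss, decade drops, dilution requirements).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    mzR,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
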