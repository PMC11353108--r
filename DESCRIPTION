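Package: tetracond
Title: Buffer-Calibrated Tetrapolar Bioimpedance Spectroscopy and Tissue
    Conductivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts tetrapolar bioimpedance spectra (3 kHz to 1 MHz) into
    tissue electrical conductivity using a saline-buffer calibration of the
    per-frequency conversion factor, and analyses cohorts of liver-tissue
    measurements: per-group conductivity summaries at selected frequencies,
    conductivity ratios between tissue classes, and tie-corrected
    Kruskal-Wallis comparisons. Includes a Cole-dispersion forward simulator
    of tetrapolar measurements (resistive reference buffers, stray
    capacitance and lead inductance, seeded cohort generation) so the whole
    pipeline is testable without clinical data, and analytical estimates of
    the radial electric-field decay around needle electrodes used to reason
    about minimal measurable tumor size.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
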