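Package: depcell
Title: Single-Shell Dielectrophoresis Spectrum Analysis of Cell
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward modelling and fitting of dielectrophoresis (DEP)
    light-intensity spectra with the single-shell (shelled-sphere)
    dielectric cell model. Computes complex permittivities and the
    Clausius-Mossotti factor, locates DEP crossover frequencies, fits
    20-point well-plate spectra by bounded multi-start least squares to
    extract effective membrane conductance, effective membrane
    capacitance and cytoplasmic conductivity, derives whole-cell
    capacitance from cell radius, simulates synthetic cohorts with
    biological and technical repeat structure, and aggregates fits into
    group summaries with unpaired two-tailed t-tests and
    parameter-recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
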