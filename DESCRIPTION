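Package: mlpaflow
Title: Quality Control, Normalisation and Copy-Number Calling for MLPA
    Fragment Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for Multiplex Ligation-dependent Probe Amplification
    (MLPA) dosage analysis from capillary fragment-analysis peak tables.
    Reads kit definitions and peak-table exports, binds peaks to probes by
    product size, computes the Q1/Q2/Q3 trace quality indicators, performs
    robust median-based row/column normalisation with MAD-driven
    calibration-probe selection among the kit reference probes, classifies
    normalised ratios into loss/normal/gain states, renders heat maps and
    per-sample ratio plots with plain-text twins, manages analyses in a
    directory-based project store with authorization freezing, and
    generates synthetic cohorts with known copy-number truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
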