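Package: breathflow
Title: Exhaled-Breath Biomarker Validation for Obstructive Sleep Apnea from
    Real-Time SESI-HRMS Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for validating targeted metabolite markers of
    obstructive sleep apnea (OSA) in exhaled breath measured by secondary
    electrospray ionization high-resolution mass spectrometry (SESI-HRMS).
    Reads raw scan streams from mzXML, recalibrates the mass axis onto a
    common reference breath spectrum, selects exhalation-phase scans by
    gating on the protonated water trimer ion, picks and aligns peaks into
    a subject-by-feature intensity matrix, matches features against a prior
    marker panel at fixed mass tolerance, tests between-group differences
    with the Mann-Whitney U test, and evaluates the panel's diagnostic value
    with cross-validated support-vector classification. Includes a synthetic
    breath-cohort generator with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    mzR,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
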