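Package: sftscreen
Title: Dual-Dye Cytotoxicity Screening, Dose-Response and Drug-Combination
    Synergy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for image-based dual-dye (live-stain /
    dead-stain) cytotoxicity screens in 384-well plates: death-fraction
    time courses, trapezoidal AUC and final-timepoint metrics, robust
    Z-score hit calling with test-population and control-based
    normalization, multi-dose selectivity/efficacy/off-target triage of
    secondary screens, four-parameter logistic dose-response fitting with
    ICx extraction, and drug-combination interaction scoring via the
    Chou-Talalay combination index, Loewe additivity and
    highest-single-agent expected-effect surfaces. Includes seeded
    synthetic-data generators with known ground truth for end-to-end
    validation, plus small utilities for two-sample t-test sample-size
    calculation, 2^-ddCt relative quantification and cell-cycle
    proliferation ratios.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
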