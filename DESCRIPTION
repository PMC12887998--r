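Package: tmtcal
Title: Proteome-Wide Multipoint Internal Calibration Curves for TMT
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing peptide-level quantitative linearity in
    isobaric (TMT) proteomics experiments that multiplex a serial dilution
    of a pooled digest alongside the biological samples. Provides readers
    for peptide/PSM-level reporter-intensity tables, reporter-ion isotopic
    impurity correction, per-peptide calibration-curve fitting with an
    iterative R-squared-thresholded linearity classifier, linear-range
    gating and regression-based calibration of endogenous intensities,
    protein-level relative quantification under all-peptide versus
    linear-only peptide selection, and a seeded synthetic-data generator
    for dilution-series experiments with additive background floors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
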