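Package: emtdx
Title: Diagnostic Accuracy and Prediction Increment of Tumor Detachment Markers
Version: 0.1.0
Authors@R:
    person("CanCORS", "Methods Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluates a primary-tumor marker of epithelial-mesenchymal
    transition (EMT) as a third diagnostic test of cancer-cell detachment,
    alongside lymph node evaluation and radiologic imaging.  Implements
    Bayesian latent class estimation of test sensitivity and specificity
    without a gold standard, with conditional dependence between tests
    modeled through a shared probit random effect, under eight dependence
    structures.  Implements risk-reclassification analysis of the marker's
    increment to 5-year mortality prediction over the established tests:
    Cox model absolute risks, censored-outcome c-index, event and non-event
    net reclassification indices, integrated discrimination improvement,
    reclassification calibration, and bootstrap confidence intervals.
    Includes a synthetic-cohort generator with known latent truth so the
    whole pipeline is testable without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
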