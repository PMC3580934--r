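Package: sler
Title: Weighted Scoring and Validation of the Revised Stressful Life Event Questionnaire
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and validating per-item integer weights for a
    46-item stressful life event (SLE) questionnaire screened against the
    GHQ-12. Implements the full derivation pipeline: a synthetic-cohort
    generator with zero-inflated ordinal item responses, mean-substitution
    feature encoding, a from-scratch feedforward neural network trained by
    gradient descent, a genetic algorithm over network architecture driven by
    a discrimination (Youden) fitness, extraction of an equivalent linear
    model, conversion of item coefficients to published-style integer weights,
    and confusion-matrix evaluation (sensitivity/specificity) of the resulting
    screening score at its cut point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
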