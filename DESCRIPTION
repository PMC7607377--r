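Package: arthrocalc
Title: Personalised Outcome and Risk Calculation for Joint Replacement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational engine for personalised decision support in hip
    and knee arthroplasty. Implements a flexible parametric
    proportional-hazards survival model with a natural cubic spline
    baseline on log time (fitted jointly by maximum likelihood), a linear
    patient-reported outcome measure (PROM) regression with a quadratic
    age term, cohort validation filters, a model registry with an
    end-to-end calculation pipeline producing a predicted post-operative
    PROM score and yearly mortality and revision risk curves, a repeated
    k-fold cross-validation harness, and a synthetic cohort generator for
    testing the whole pipeline without access to registry data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
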