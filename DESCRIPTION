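Package: uvsdt
Title: Unequal-Variance Signal Detection Analysis from Response Times and
    Confidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for type-1 receiver operating characteristic (ROC)
    analysis of yes/no detection data under the unequal-variance Gaussian
    signal detection model. Trial-level records are converted to 2 x 2n
    response-frequency tables by per-subject confidence discretization or
    response-time quantile binning (treating faster responses as stronger
    evidence for the chosen option), the model is fitted by maximum
    likelihood with ordered response criteria, and the bias-robust
    sensitivity index d_a is reported alongside conventional d-prime and
    the criterion c. Includes a generative unequal-variance observer
    simulator with a monotone evidence-to-response-time mechanism, empirical
    ROC/zROC construction, cohort-level summaries comparing response-time-
    and confidence-based estimates, and a reproducible file-based pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
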