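Package: smsengage
Title: Content Analysis and Engagement Modelling for SMS-Based Health Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing communication logs from SMS text-message
    health-support programs. Groups near-duplicate outgoing messages by
    stemmed-token Jaccard similarity, classifies message intent and
    participant reply categories with an L2-regularised multinomial linear
    model evaluated under group-constrained nested cross-validation,
    computes confusion-matrix metrics, balanced accuracy and one-vs-rest
    ROC curves, derives premature-stop and engagement outcomes per
    participant, and estimates intent-outcome odds ratios with
    program-type interactions. Includes a seeded synthetic
    communication-log generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    tibble,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
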