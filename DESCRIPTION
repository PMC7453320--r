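Package: ewsmonitor
Title: Personalized Early-Warning-Sign Monitoring from Momentary Symptom Self-Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An engine for active symptom monitoring in psychosis via
    ecological momentary assessment (EMA): semi-random prompt scheduling,
    personalized early-warning-sign (EWS) scoring with tiered relevance
    weights and threshold alert rules, adherence and retention metrics,
    alert-performance evaluation (sensitivity, specificity, positive
    predictive value), and trial design statistics (two-proportion power
    with dropout inflation, baseline-adjusted ANCOVA treatment effects).
    Includes a synthetic symptom-trajectory simulator with ground-truth
    relapse prodromes for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
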