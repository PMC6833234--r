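Package: pphypo
Title: Postprandial Hypoglycemia Prediction from Continuous Glucose Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict postprandial hypoglycemia from continuous glucose
    monitoring (CGM) traces and meal announcements. Provides CGM preprocessing
    (cubic-spline gap filling, nocturnal meal filtering, meal merging), extraction
    of a three-feature set (glucose at prediction time, rate of increase in
    glucose after a meal, glucose rate of change) with 30-minute-horizon labels,
    cost-sensitive training of five classifier families under cross-subject
    k-fold validation, sample-level metrics (sensitivity, specificity, precision,
    F1, ROC/AUC) and an event-level alarm calculus (hypoglycemic events, alarms,
    false alarm rate, detection time, severity strata). A synthetic CGM cohort
    generator reproducing four postprandial response archetypes makes the full
    pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    e1071,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
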