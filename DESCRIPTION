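Package: ppgrclust
Title: Meal-Based Clustering of Postprandial Glycemic Responses from
    Continuous Glucose Monitor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Isolates 4-hour postprandial glycemic response (PPGR) windows
    from 5-minute continuous glucose monitor (CGM) traces, categorizes them
    into clock-time meal bands (breakfast, lunch, snack, dinner), and groups
    them by a greedy coefficient-of-variation (CV) threshold rule: events
    join a cluster only while the pooled CV of the cluster's glucose values,
    referenced to the participant's meal-category mean, stays below a
    clinical threshold (36 percent by default).  Includes mealtime
    imputation from weekday habits, meal/correction bolus classification,
    per-cluster evaluation metrics (SD, SE, internal CV, peak and
    carbohydrate summaries against a 0.8 mmol/L sensor-error reference),
    a first-principles one-way ANOVA of carbohydrate intake across
    clusters, a noncentral-t power solver for standardized effect sizes, a
    synthetic CGM generator with planted response templates for method
    validation, and a reproducible end-to-end pipeline with CSV/JSON
    outputs.  Readers are provided for an OhioT1DM-style per-participant
    XML dialect and a generic CSV dialect; no restricted data are bundled.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    yaml,
    withr,
    mclust
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
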