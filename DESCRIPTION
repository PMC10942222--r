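Package: surgesture
Title: Surgical Gesture Timeline Features and Skill Classification for
    Laparoscopic Cholecystectomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for annotation-based surgical skill assessment in
    laparoscopic cholecystectomy. Models annotated gesture ("Surgesture")
    timelines of the two critical dissection phases, extracts a 63-feature
    representation (per-category counts and durations, inter-event
    intervals, gesture shift frequencies, dissection/exposure ratios and
    manipulation time), aggregates modified-GOALS ratings with inter-rater
    reliability checks (ICC, Kendall's W), derives quantile skill groups,
    compares groups statistically, and classifies competent versus
    incompetent performance with five cross-validated classical models,
    class-balancing timeline augmentation and feature-importance mining.
    Includes a semi-Markov synthetic cohort generator so the whole pipeline
    is testable without access to clinical video annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    glmnet,
    jsonlite,
    randomForest,
    rpart,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
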