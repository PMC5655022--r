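Package: playprogress
Title: Therapy Progress Recognition from Tablet-Game Behavioural Telemetry
Version: 0.1.0
Authors@R:
    person("AUTMON", "Replication Project", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for recognizing therapy progress in children with autism
    spectrum disorder from behavioural data recorded by five tablet games.
    Provides a session data model with a JSON Lines on-disk format, kinematic
    signal operators over touch paths and inertial series, per-game feature
    extractors conforming to a canonical 182-entry registry, questionnaire
    scoring into ten developmental-area evaluations, session-difference
    dataset construction with normalization and PCA, a classifier suite
    (decision tree, naive Bayes, tree-augmented naive Bayes, neural network,
    random forest, bagging, AdaBoost, rotation forest) evaluated with
    repeated stratified cross-validation and t-based confidence intervals,
    correlation and information-gain feature ranking, and a latent-skill
    cohort simulator for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
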