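Package: ordifuzz
Title: User-Informed Fuzzy Encodings for Ordinal Severity Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts elicited perceptions of ordinal severity labels
    (intervals and representative points on a 0-100 visual-analogue
    continuum) into discrete fuzzy-set representations, derives scalar and
    vector feature encodings from them (centroid defuzzification, weighted
    sampling, membership vectors) alongside classical ordinal baselines,
    compares perception distributions across rater strata with
    nonparametric two-sample tests, and benchmarks the encodings in a
    nested cross-validated regression harness. Includes seeded synthetic
    generators for elicitation surveys and a latent-severity outcome
    dataset, plus a command-line pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    randomForest,
    glmnet,
    e1071,
    caret
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
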