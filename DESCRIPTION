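Package: pausefake
Title: Deepfake Voice Detection from Speech Pause Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discriminates cloned (deepfake) voice recordings from authentic
    human speech using amplitude-agnostic pause-pattern features. Provides WAV
    input/output, a deterministic energy-based voice activity detector with a
    pluggable segmenter contract, five pause-profile features (mean and SD of
    speech-segment length, proportion of time speaking, and micro- and
    macropause rates), nonparametric class comparison, five classical
    classifiers tuned under participant-grouped stratified cross-validation,
    model-naive subgroup evaluation with confusion-matrix reporting, and a
    synthetic speech-timeline simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    rpart,
    randomForest,
    e1071,
    glmnet,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
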