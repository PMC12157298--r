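Package: dynsit
Title: Sitting-Posture Classification and Dynamic-Sitting Reminder Engine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computational core of a textile-sensor smart garment for
    sitting-posture monitoring. Provides a synthetic generator for
    4-channel capacitive strain-sensor signals with the acquisition
    protocol of a multi-participant posture study, preprocessing
    (validity filtering, label encoding, min-max normalization,
    stratified splitting), a grid-search / cross-validation benchmark of
    four classifier families (k-nearest neighbours, RBF support vector
    machine, decision tree, random forest), a hazard-tiered reminder
    state machine that converts per-second posture classifications into
    haptic feedback events, and session reporting with a paired
    before/after intervention comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    class,
    e1071,
    jsonlite,
    randomForest,
    rpart,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
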