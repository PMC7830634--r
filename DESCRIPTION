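Package: fogpredict
Title: Detection and Prediction of Freezing of Gait from Shank Angular Velocity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Step-to-step analysis of shank gyroscope recordings for the
    detection and short-horizon prediction of freezing of gait (FOG) in
    Parkinson's disease. Provides mean-range signal normalization, two-device
    synchronization via the sit-to-stand transient, mid-swing peak detection
    and step segmentation, a 16-feature step descriptor set spanning time and
    frequency domains (including dynamic-time-warping stride similarity and
    spectral entropy), decision-tree wrapper feature ranking, cost-sensitive
    classifiers (SVM, kNN, regularized LDA, regularized logistic regression),
    leave-one-subject-out and repeated split validation protocols,
    cross-therapy-condition transfer experiments, and confusion/ROC-based
    performance reporting. A synthetic two-shin gait simulator with
    configurable pre-FOG degradation and FOG phenotypes supports end-to-end
    testing without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    rpart,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
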