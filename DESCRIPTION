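Package: psgApnea
Title: Epoch-Level Detection and Distinction of Sleep Apnea Events from
    Multi-Channel Polysomnography
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for recognising sleep apnea events in
    30-second polysomnography (PSG) epochs using low-invasive channels
    (thoracic respiratory effort, pulse oximetry, audio, EOG, ECG, body
    position). Provides a seeded generator of annotated synthetic PSG
    recordings with planted obstructive, central, mixed apnea and hypopnea
    events; epoch segmentation, exclusion and labelling; a named bank of
    time, frequency, complexity, hypoxic-burden and heart-rate features
    with fixed 32- and 44-feature registries; covariance-PCA feature
    selection with MANOVA group-mean dendrograms; subject-wise balanced
    dichotomous case studies; and tuned classical classifiers (decision
    tree, discriminant analysis, naive Bayes, SVM, kNN) reported as
    sensitivity, specificity, predictive values and accuracy over repeated
    evaluations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    Rcpp,
    e1071,
    MASS,
    class,
    rpart,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
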