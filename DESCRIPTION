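Package: eegBoDF
Title: Wavelet Scalogram and Bag-of-Deep-Features Pipeline for EEG Emotion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for recognising emotional state
    (negative, neutral, positive) from multi-channel EEG. One-dimensional
    EEG windows are decomposed into continuous-wavelet-transform scalograms,
    rendered as colour images and summarised by a pluggable feature
    extractor (a deterministic multi-scale grid-statistics extractor is
    bundled). Channels are ranked and selected with a rough-set
    conditional-entropy criterion over discretized features, the retained
    feature vectors are quantised against per-class k-means vocabularies
    (Bag of Deep Features) into compact count histograms, and the
    histograms are classified with SVM, k-NN, decision-tree and
    random-subspace ensemble learners under stratified cross-validation.
    A synthetic EEG generator with class-dependent band-power structure
    emulates a SEED-style recording layout so the whole pipeline is
    testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    class,
    rpart,
    EBImage,
    rhdf5,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
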