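Package: eegcaps
Title: EEG Seizure Classification with Capsule and Transformer Heads on a 1-D
    Convolutional Backbone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification of single-channel EEG segments (seizure versus
    non-seizure, and five recording conditions) with a 1-D convolutional
    feature extractor feeding one of several heads: a dense stack, a capsule
    layer with dynamic routing-by-agreement, a transformer encoder, or their
    combinations. The network engine (convolution, batch normalisation, SELU,
    max pooling, dropout, layer normalisation, multi-head self-attention,
    capsule routing, Adam) is implemented in plain R with hand-derived
    gradients so every primitive is testable against naive oracles. Includes
    restructuring of 4097-sample recordings into 178-sample segments,
    standardisation and PCA preprocessing fit on training data only,
    from-scratch SMOTE and ADASYN minority oversampling, stratified k-fold
    cross-validation and per-class metrics, 1-D Grad-CAM saliency maps, a
    synthetic EEG segment generator, and a thin comparison harness over
    classical machine-learning models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    caret,
    rpart,
    nnet,
    randomForest,
    ranger,
    e1071,
    xgboost,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
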