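Package: somnostage
Title: Sleep Stage Classification from Polysomnography with Temporal,
    Spectral and Nonlinear Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automatic sleep staging from multi-channel
    polysomnography (EEG, EOG, EMG). Implements Hamming-window FIR
    band-pass filtering, 30-second epoch extraction against expert
    hypnograms, per-epoch feature extraction (Welch power spectral
    density, singular value decomposition entropy, Higuchi fractal
    dimension, permutation entropy, detrended fluctuation analysis and
    statistical moments), SMOTE rebalancing of training data, and
    cross-validated multi-class classification with gradient-boosted and
    randomized tree ensembles over five sleep-stage configurations.
    Includes a stage-aware synthetic polysomnography generator and
    minimal EDF/EDF+ readers and writers so the whole pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    withr,
    xgboost,
    randomForest,
    ranger,
    pROC
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'synthetic.R'
    'edf.R'
    'io.R'
    'stages.R'
    'filter.R'
    'epochs.R'
    'features.R'
    'smote.R'
    'learners.R'
    'modeling.R'
    'pipeline.R'
RoxygenNote: 7.3.3
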