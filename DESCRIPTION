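Package: plmdetect
Title: Detection of Periodic Leg Movements from Polysomnography Without Leg EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for detecting periodic leg movement (PLM) epochs in
    polysomnography (PSG) using every recorded channel except leg
    electromyography. Provides EDF signal and XML/JSON annotation input and
    output, a synthetic PSG generator with ground-truth Coleman-compliant
    PLM trains and configurable coupling of movements into non-leg channels,
    Coleman-rule PLM scoring of leg EMG for ground-truth labels, 5-second
    epoch segmentation with artefact, apnea-adjacency and wakefulness
    exclusion, class balancing with per-patient stratified subsampling, a
    77-attribute digital-signal-processing feature extractor (Haar wavelet
    EEG subbands, DFT spectra, spectral entropy, oximetry and contextual
    features), gain-ratio attribute ranking, and evaluation of k-nearest
    neighbour, random forest, multilayer perceptron and ridge logistic
    regression classifiers under repeated stratified 10-fold
    cross-validation with confusion matrices, accuracy and probabilistic
    RMSE.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    class,
    randomForest,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
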