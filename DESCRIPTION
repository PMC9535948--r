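Package: spliceStack
Title: Stacking Ensembles of Small Neural Networks for Splice-Site Prediction
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects donor (GT) and acceptor (AG) splice sites in fixed-length
    genomic DNA windows with a stacking ensemble: eight small convolutional and
    dense neural sub-models produce binary votes that a logistic-regression
    meta-model combines into a final call. Includes readers for the common
    140-nt and 602-nt labelled window dialects, one-hot encoding, a seeded
    position-weight-matrix simulator of splice-window datasets, stratified
    five-fold cross-validation with classifier-diversity metrics (Q-statistic,
    disagreement, double fault, correlation) for ensemble selection,
    position-frequency-matrix export for sequence logos, occlusion-based
    importance scores, and a command-line interface. The neural-network engine
    (1-D convolution, max-pooling, dropout, dense layers, Adam with an
    inverse-time-decay learning-rate schedule) is implemented in R on top of
    BLAS matrix products.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
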