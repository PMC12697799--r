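Package: ncrtools
Title: Neural Code Reliability Decoding of Complex Sounds from Spike Trains
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs a continuous complex-sound spectrogram from spike
    trains by averaging the stimulus segments behind the k most similar
    spiking patterns and scores the reconstruction by the Neural Code
    Reliability (NCR) metric, the log10 absolute Pearson correlation
    between actual and decoded stimuli. Provides temporal (Hann-smoothed
    spike trace) and rate (window spike count) codes, group decoding by
    concatenation, lag and window-size scans, Poisson null calibration of
    the significance threshold, per-frequency synergy/redundancy
    decomposition for neuron pairs with silence, spikes-only and
    combinatorial restrictions, spectrotemporal receptive field (STRF)
    construction and feature extraction, stimulus-complexity statistics,
    and a synthetic stimulus (random double sweep) plus model-neuron
    (Poisson and linear-nonlinear-Poisson) toolkit with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'utils.R'
    'codes.R'
    'complexity.R'
    'stimulus.R'
    'strf.R'
    'engine.R'
    'pair.R'
    'demo.R'
    'io.R'
    'neurons.R'
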