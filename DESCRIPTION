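Package: fusemix
Title: Fusion Mixture Feature Extraction and Hybrid Swarm Classification for Biosignals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for classifying sampled biosignals such as EEG segments.
    Raw signals are summarised by moment and entropy descriptors, modelled by a
    fusion of finite mixture families (uniform-normal, ensemble uniform-normal,
    and exponential-tail normal mixtures) fitted by intensity-weighted EM with
    BIC/AIC model selection and a local false-discovery-rate rule for retaining
    differential observations. Feature subsets are chosen by a hybrid
    differential-evolution / particle-swarm / bee-colony optimizer with
    elitism, and segments are classified either by a zero-inflated Poisson
    mixture regression model with concomitant component weights or by a
    bidirectional LSTM trained with Adam. Includes seeded synthetic-signal
    generators and a stratified k-fold cross-validation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    MASS,
    mclust,
    pracma,
    optparse
Config/testthat/edition: 3
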