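Package: entrofatigue
Title: Entropy Features and Classifier Comparison for EEG Driver-Fatigue Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-channel EEG driver-fatigue analysis pipeline: four
    entropy features (sample, approximate, fuzzy and spectral entropy),
    notch/band-pass preprocessing and 1-s epoching, a harness over ten
    standard classifiers with leave-one-epoch-out cross-validation, and
    ranking of channel x feature x classifier combinations. Includes a
    synthetic two-state (normal vs fatigue) EEG generator with a tunable
    regularity contrast so the full pipeline is testable without access
    to recordings, plus TSV and EDF recording I/O.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    signal,
    class,
    e1071,
    kernlab,
    rpart,
    ranger,
    nnet,
    MASS,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
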