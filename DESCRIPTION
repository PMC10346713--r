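Package: trialcv
Title: Quantifying Temporal-Correlation Leakage in Cross-Validation of
    Trial-Structured Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring how within-trial temporal correlation biases
    k-fold cross-validation in single-subject classification of
    trial-structured physiological time series (e.g. EEG-based passive
    brain-computer interface designs), and how block-wise (trial-wise)
    cross-validation behaves in the same settings.  Provides a synthetic
    session generator with controllable class separability and within-trial
    correlation, band-power, differential-entropy, spectral-entropy and RMS
    feature extraction with fold-safe z-scoring, mRMR feature selection,
    LDA, linear-SVM and KNN classifier contracts, sample-level k-fold and
    trial-level block-wise cross-validation with trial- and sample-level
    label-randomization diagnostics, and t-test based report grids comparing
    accuracies against ground truth and chance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    class,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
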