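Package: drowsEEG
Title: Hybrid CNN-SVM Drowsiness Detection from EEG Scalograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for EEG-based vigilance monitoring: a synthetic
    vigilance-EEG simulator with state-dependent band power, EDF reading
    and writing, zero-phase FIR band-pass preprocessing, 30-second
    segmentation with Karolinska Sleepiness Scale label binarisation,
    Morlet continuous-wavelet-transform scalogram images, a lightweight
    2D convolutional network feature extractor trained with Adam and
    binary cross-entropy, support-vector-machine classification heads
    with grid-searched hyperparameters, and confusion-matrix based
    evaluation with precision-recall and ROC curves. Includes experiment
    drivers for network-depth ablation and SVM-kernel comparison and a
    command-line pipeline for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    grDevices,
    jsonlite,
    png,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
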