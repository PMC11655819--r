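Package: latstep
Title: Stepwise Latency Correction and Classifier-Based Assessment of Single-Trial ERPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for disentangling latency and amplitude effects in event-related
    potentials (ERPs) at the single-trial level. Implements a residue-iteration
    decomposition of epoched EEG into stimulus-locked (S), latency-variable central
    (C) and response-locked (R) component clusters, followed by a four-step latency
    correction pipeline: within-condition jitter correction, between-condition and
    between-subject peak-latency synchronization at a reference electrode, and
    global field power (GFP) amplitude normalization. The impact of each correction
    stage on condition information is assessed with cross-validated classifiers (a
    compact convolutional network and a regularized logistic baseline), sliding
    window temporal decoding, temporal generalization matrices, and DeepLIFT-style
    saliency maps. A ground-truth ERP simulator generates epoched data with
    controllable component morphology, topography, latency jitter, condition
    latency shifts and reaction-time locking for validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
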