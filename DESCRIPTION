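Package: neurorp
Title: Recurrence-Plot Based Hybrid EEG-fNIRS Mental Workload Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying mental-workload states from simultaneous
    EEG and functional near-infrared spectroscopy (fNIRS) recordings of an
    n-back working-memory protocol. Labeled signal windows are projected into
    phase space by time-delay embedding and converted to recurrence-plot
    image sequences, one per modality, so that the two modalities are fused
    without resampling either one to the other's rate. A time-distributed
    convolutional network feeding a long short-term memory layer classifies
    the image sequences into four states (0-back, 2-back, 3-back, rest),
    evaluated by stratified k-fold cross-validation. Includes a synthetic
    generator for simultaneous EEG + two-wavelength fNIRS n-back sessions,
    readers and writers for EDF and SNIRF, zero-phase Butterworth filtering,
    and the modified Beer-Lambert conversion from optical density to
    hemoglobin concentration changes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    rhdf5,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'core_io.R'
    'edf.R'
    'evaluate.R'
    'model.R'
    'neurorp-package.R'
    'pipeline.R'
    'preprocess.R'
    'recurrence.R'
    'synthgen.R'
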