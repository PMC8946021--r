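Package: cardiocs
Title: Compressed Sensing Acquisition and Dictionary-Based Reconstruction of ECG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compressive acquisition and sparse reconstruction of
    single-lead electrocardiograms. Implements two acquisition schemes: classical
    compressed sensing of fixed 300-sample frames with a patient-specific
    dictionary, and cardiac-pattern compressed sensing in which beats are
    segmented at RR-interval midpoints, resampled to 301 samples, optionally
    R-wave centred, and reconstructed against universal (mega), pathology-specific
    or patient-specific pattern dictionaries. Includes Gaussian, symmetric
    Bernoulli and dictionary-optimized sensing matrices, an interior-point
    basis-pursuit solver, compressed-domain and reconstruction-domain beat
    classifiers (alpha-max, k-nearest-neighbour, multilayer perceptron),
    PRD/PRDN/CR/QS distortion scoring, a synthetic annotated ECG generator for
    fully reproducible experiments, and readers/writers for WFDB and CSV records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml,
    nnet
Suggests:
    testthat (>= 3.0.0),
    class,
    withr,
    optparse
Config/testthat/edition: 3
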