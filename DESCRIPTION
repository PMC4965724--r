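Package: semgrip
Title: Surface-EMG Grip and Movement Recognition with Symbolic Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A pipeline for recognizing hand grips and movements from
    multichannel surface electromyograms (sEMG). Raw 8-channel recordings are
    reduced to mean-absolute-value (MAV) feature streams, labeled with the help
    of hand-mounted accelerometers, discretized into 8-letter symbolic words by
    per-channel equal-probability binning, and classified three ways: per-instance
    baseline classifiers, a class-by-word affinity matrix with a temporal
    summation window, and banded dynamic time warping over word sequences with a
    modified lexical local cost. Includes a protocol simulator that generates
    synthetic recordings with known ground truth for an 8-run, 25-class
    grip/movement collection protocol, plus leave-one-repetition-out and
    stratified cross-validation evaluation harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp,
    randomForest,
    e1071,
    rpart,
    class
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
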