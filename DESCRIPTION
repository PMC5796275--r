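Package: gaitseg
Title: Stride Segmentation Methods for Foot-Worn Inertial Sensor Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for segmenting strides in foot-worn inertial measurement
    unit (IMU) recordings of gait, with a focus on Parkinsonian walking tests.
    Implements four segmentation methods side by side: gyroscope mid-swing peak
    detection with amplitude threshold and refractory period, multi-subsequence
    dynamic time warping against an averaged Euclidean stride template and
    against a per-position Gaussian (probabilistic) template, and a two-level
    hierarchical hidden Markov model with Hann-window features, PCA, Gaussian
    mixture emissions, semi-supervised Baum-Welch training and Viterbi
    decoding. Includes a parametric synthetic gait generator (straight walks
    and Timed Up-and-Go style sequences with rests, postural transitions and
    turning strides), tolerance-based event matching with precision, recall and
    F-score, leave-one-subject-out and nested subject-level cross-validation,
    grid search, and pairwise Wilcoxon signed-rank comparison of methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
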