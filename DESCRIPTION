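Package: audiencesync
Title: Inter-Subject Correlation Analysis of Audience Physiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring physiological synchrony in audiences watching
    the same media. Preprocesses heart-rate, skin-conductance and accelerometer
    recordings to clean 1 Hz series; computes sliding-window inter-subject
    correlations (ISC) within and between stimulus-modality groups; assesses
    per-participant significance with circular-shuffle permutation nulls under
    Benjamini-Hochberg false-discovery-rate control; extracts low-level
    audiovisual salience features (conspicuity-channel RMS and RMS volume) and
    compares narrative against low-level predictors of condition-level heart
    rate by nested regression and BIC; relates ISC time courses to interval
    probed immersion ratings. A synthetic-data module generates audiences,
    stimuli and rating cohorts with known ground truth so every stage is
    testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    yaml,
    Rcpp,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
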