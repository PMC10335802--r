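Package: bcistream
Title: Stream-Based EEG Processing and Riemannian Classification for
    Closed-Loop Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("BCI", "Stream Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A testable computational core for human-in-the-loop EEG
    experiments: rate-scheduled acyclic stream-processing graphs with
    publish/subscribe messaging, causal FIR filtering, event-locked and
    rolling-window epoching, baselining, covariance features on the manifold
    of symmetric positive-definite matrices with minimum-distance-to-mean
    classification, an unsupervised oddball (P300) target detector,
    stimulus-to-EEG latency calibration from tap artifacts, XDF/CSV
    recording, and a seeded synthetic EEG generator so that complete motor
    imagery and oddball sessions run end-to-end without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
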