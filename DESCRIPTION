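Package: harkit
Title: Human Activity Recognition Toolkit: Level-Set Segmentation,
    Silhouette HMMs, Semi-Markov CRFs and Rule-Based Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational building blocks for sensor-based human activity
    recognition in smart-home and tele-care settings. Provides region-based
    active-contour body segmentation that augments the Chan-Vese energy with
    an area-scaled Bhattacharyya separation term; a silhouette video
    classifier built from independent-component motion features, vector
    quantization and discrete hidden Markov models; a null-activity-aware
    semi-Markov conditional random field with exact small-instance oracles,
    fast gradients and maximum-probability decoding for wearable sensor
    streams; an executable rule engine that lifts low-level activity events
    to high-level activities, reminders and device commands; and seeded
    synthetic generators so that every component is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
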