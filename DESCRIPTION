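Package: trunksense
Title: Trunk Posture Monitoring, Multisensory Feedback and Session Analytics from Chest-Worn Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless re-implementation of a smartphone-based trunk posture
    monitor for rehabilitation. Estimates signed frontal (sagittal-plane) and
    lateral (coronal-plane) trunk deviation angles from 3-axis accelerometer
    streams relative to a calibrated best-at-the-time posture, drives a
    configurable multisensory feedback state machine (color change, vibration,
    directional audio after a tolerance window, periodic praise, congratulation
    on return), records timestamped session logs in an OpenMHealth-style JSON
    envelope, derives per-stage session metrics (maintained positions,
    corrective movements, time in posture) with two-condition statistical
    comparisons, and ships a synthetic trunk-movement simulator with
    rotation-matrix ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
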