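Package: tolsense
Title: Time-on-Legs and Posture Detection from a Necklace-Worn Hybrid Motion Sensor
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects time-on-legs (ToL) and mobility-related postures
    (sitting, standing, walking, lying) in older adults from a necklace-worn
    hybrid sensor combining a tri-axial accelerometer (50 Hz, +/-4 g) with a
    barometric pressure sensor (25 Hz). Implements the per-modality detectors
    (activity intensity, sit/stand transfers via an SVM on template
    cross-correlation and barometric altitude-change features, step-peak
    walking detection, orientation-based lying detection), the heuristic
    second-by-second fusion classifier with its priority and context rules,
    and second-by-second validation statistics against annotated ground truth
    (sensitivity, specificity, overall agreement with qualitative grades,
    ICC(2,k) inter-rater reliability, frail versus non-frail comparison).
    A synthetic-recording generator scripts standardized mobility protocols
    and free-movement sessions for frail and non-frail subject profiles and
    synthesizes paired sensor signals with ground-truth annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    e1071,
    pracma,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
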