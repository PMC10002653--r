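Package: larvawalk
Title: Simulation and Analysis of Long-Term Larval Crawling Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying Drosophila larva crawling behavior over
    multi-hour recordings in a robot-assisted arena. Provides an agent-based
    simulator of run-and-turn locomotion under an optional linear thermal
    gradient (klinokinesis), a stochastic model of the edge-triggered
    pick-up/drop-off transport robot, a sparse-pixel frame renderer, blob
    detection and identity-preserving tracking with dropped-frame
    interpolation, midline/head-tail posture estimation with temporal flip
    suppression, bidirectional run/turn segmentation, derived behavioral
    features (speed, curvature, turn rate, turn size, handedness, navigation
    index), peri-event transient analysis, trajectory stitching, and
    intra- vs inter-animal variability analysis with Sarle's bimodality
    coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
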