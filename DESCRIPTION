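Package: warpkit
Title: Simulation and Analysis of Perceptual Warping in Speech Categorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying context-dependent shifts ("warping") of the
    category boundary in two-alternative speech identification. Provides a
    cascade formant synthesizer for vowel continua with speech-shaped
    (long-term power spectrum matched) masking noise and exact SNR mixing; a
    parametric synthetic observer that generates identification responses,
    reaction times and 100 Hz mouse-cursor trajectories under random and
    serial stimulus orders; psychometric sigmoid fitting (boundary and slope),
    reaction-time profiling and split-half reliability; mouse-tracking
    geometry (time normalization, mirroring, area under the curve, Euclidean
    proximity over normalized time, running paired t-tests); and
    repeated-measures ANOVA, Holm-adjusted contrasts and correlation analyses
    linking boundary shifts to trajectory curvature. A single-call pipeline
    reproduces the full analysis from a JSON configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
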