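Package: penlaws
Title: Kinematic Laws of Handwriting from Pen Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies three motor laws of handwriting -- isochrony
    (speed scales with gesture size so duration stays constant),
    homothety (the fraction of time devoted to each element of a word
    or symbol sequence is preserved across sizes and speeds), and the
    speed-accuracy tradeoff formalised by the steering law (movement
    time grows linearly with the index of difficulty of a constrained
    path) -- from timestamped pen trajectories recorded on consumer
    tablets.  Includes a validated session file format (CSV and JSON),
    copy-task kinematics (border trimming, path length, low-pass
    filtered speed), cursive-word and symbol-sequence segmentation,
    tunnel-task movement-time extraction with trial exclusion rules,
    per-subject steering-law regression, a nonparametric statistical
    battery (Wilcoxon matched pairs, Friedman with Bonferroni post hoc,
    Mann-Whitney U) with exact small-sample p-values, and a seedable
    synthetic cohort generator with configurable adherence to each law
    so that every pipeline stage is testable without child recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
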