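Package: pupilgaze
Title: Pupillometry and Microsaccade Analysis for Listening-Effort Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for task-evoked pupillometry in cognitive
    hearing science: blink and outlier artifact handling, linear
    interpolation, trial exclusion, Kaiser-window FIR low-pass filtering and
    baseline correction of pupil-area traces; sentence-locked mean/peak
    dilation and peak-latency metrics; velocity-threshold microsaccade
    detection with Gaussian-kernel rate curves; acoustic masker construction
    (multi-talker babble, envelope-modulated pink noise, RMS-exact SNR
    mixing); from-scratch 2x2 within-subject and split-plot mixed ANOVAs with
    partial eta squared, simple effects, effect-magnitude contrasts and
    partial correlations; and a synthetic eye-tracking data generator that
    makes every stage verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
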