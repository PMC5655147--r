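Package: lfpcoupling
Title: Ripple-Spindle Coupling Analysis for Dual-Site Rodent LFP Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and coupling analysis of sleep oscillations in
    dual-site local field potential (LFP) recordings from hippocampal CA1
    and anterior cingulate cortex (ACC), with an electromyogram (EMG)
    channel for behavioural state. Provides EMG/theta-delta sleep staging,
    Hilbert-envelope threshold detection of sharp-wave ripples
    (100-250 Hz), sleep spindles (12-15 Hz) and delta waves (1-4 Hz)
    restricted to NREM sleep, Welch band-power summaries, and three
    measures of ripple-spindle coupling: the amplitude cross-correlogram
    with a circular-shift shuffle null, the event-timestamp
    cross-correlogram, and the joint occurrence rate. A seeded synthetic
    three-channel recording generator with ground-truth hypnograms,
    implanted oscillatory events and controllable ripple-spindle coupling
    supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
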