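Package: affectstream
Title: Streaming EEG Emotion Classification with Prequential Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A streaming pipeline for binary valence/arousal classification
    from consumer-grade wearable EEG devices. Provides device profiles
    (Muse S, Neurosity Crown, Emotiv EPOC), per-window preprocessing
    (IIR notch, Butterworth band-pass, common average reference),
    tumbling-window Welch band-power features, interval-based delayed
    label matching, incremental classifiers (online logistic regression,
    adaptive random forest, streaming random patches), and both immediate
    (test-then-train) and delayed prequential evaluation. A seeded
    synthetic-session generator emulates band-power-modulated EEG under a
    balanced video-stimulus schedule so the whole pipeline can be
    exercised without access to restricted recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
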