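Package: haptic
Title: High-Amplitude Pilot-Tone Cardiac and Respiratory Gating with
    Interference Cancellation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts cardiac and respiratory navigators from the amplitude
    modulation of a high-amplitude pilot-tone carrier recorded in multi-coil
    MRI raw data, and removes the resulting carrier interference from imaging
    k-space using sniffer-coil based EDITER cancellation or a sinusoid-model
    baseline. Includes per-line carrier frequency/amplitude estimation,
    spiral-angle detrending, Savitzky-Golay denoising, band-pass splitting,
    correlation-based channel selection, SOBI respiratory and PCA cardiac
    source extraction, derivative-based trigger detection with prominence and
    refractory rules, trigger matching and jitter/failure-rate metrics,
    retrospective cardiac/respiratory binning, density-compensated gridding
    reconstruction with view sharing, noise-ratio evaluation, and a
    golden-angle spiral acquisition simulator that provides ground truth for
    every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
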