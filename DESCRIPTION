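Package: rhymetrf
Title: Forward TRF Analysis of Acoustic and Phonetic Encoding in Continuous Sung Speech
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the cortical encoding of continuous (sung)
    speech with forward temporal response function (TRF) models. Builds
    time-aligned stimulus representations (Greenwood-spaced auditory
    spectrogram, half-wave-rectified envelope derivative, binary articulatory
    phonetic features, visual motion), conditions multi-channel EEG (zero-phase
    Butterworth filtering, resampling, bad-channel interpolation, mastoid
    re-referencing, grand-average ground-truth traces), estimates multivariate
    lagged ridge (Tikhonov) regressions with nested leave-one-trial-out
    cross-validation, and quantifies acoustically invariant phonetic encoding
    as the EEG prediction gain of an acoustic-phonetic model over an
    acoustic-only model (FS-S). Includes the repeated-measures statistical
    battery (rmANOVA with Greenhouse-Geisser correction, Friedman with
    Kendall's W, Wilcoxon signed-rank, BH-FDR, topography bootstrap) and a
    fully synthetic longitudinal EEG cohort generator with known convolution
    kernels for end-to-end validation.
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
    withr,
    ggplot2
Config/testthat/edition: 3
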