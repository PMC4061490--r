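Package: perfspec
Title: Estimating Slow Fluctuations in Task Performance from EEG Log Power Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating slow, endogenous fluctuations in behavioral
    performance (driving lane deviation; rapid-serial-visual-presentation
    accuracy, reaction time, and button-press duration) from concurrent EEG
    log power spectra. Implements sliding-window power spectral density
    estimation with median-filter artifact mitigation, principal-component
    regression of behavior on stacked per-channel log spectra, adaptive
    channel selection by sequential forward floating selection (SFFS),
    leave-one-block-out cross-validation with permutation significance
    testing, per-frequency spectral-weight decomposition with false discovery
    rate control, and a synthetic session simulator (latent alertness state
    coupled to EEG band power and behavior) so the full pipeline can be
    exercised and validated without recorded EEG.
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
RoxygenNote: 7.3.3
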