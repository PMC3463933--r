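Package: wentaf
Title: Wavelet Entropy Analysis of Atrial Fibrillation Organization from
    Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the organization of atrial fibrillatory (f) waves
    from a single surface ECG lead using Wavelet Entropy: zero-phase
    preprocessing (baseline, high-frequency and powerline removal),
    adaptive singular-value QRST cancellation to expose the atrial
    activity, a seven-level discrete wavelet decomposition whose relative
    subband energies yield a Shannon-entropy organization score, and an
    evaluation harness (ROC-optimal thresholding, repeated stratified
    2-fold cross-validation, group statistics). Includes a synthetic
    AF-signal generator with a controllable organization level so the
    whole chain is testable without clinical recordings, plus WFDB and
    CSV record input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    car,
    withr,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
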