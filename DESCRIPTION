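Package: scedr
Title: Spectral-Continuity ECG-Derived Respiration from Heart Rate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts breathing rate and a reconstructed breathing signal
    from heart rate alone by tracking the respiratory sinus arrhythmia
    (RSA) component through a generalized Morse wavelet time-frequency
    map. The spectral-continuity method (scEDR) links per-slice spectral
    peaks into long-lasting frequency tracks and selects the most
    persistent one as the respiratory component, which makes it robust to
    transient spectral interference that defeats the classical max-power
    ECG-derived-respiration baseline (also provided). Includes R-peak
    detection and instantaneous heart-rate gridding, crest-based
    breathing-rate extraction from pressure flow channels (the validation
    gold standard), epoch-wise error evaluation against the gold
    standard, HRV band powers and LF/HF, VLF/HF ratios, a heart-rate- and
    EEG-variability-based REM0 sleep-stage reassignment, a synthetic
    cardiorespiratory signal generator with known ground truth, and
    minimal EDF input/output for polysomnography channels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
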