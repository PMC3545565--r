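Package: rftkit
Title: Cardiorespiratory Signal Processing and Resonance-Frequency
    Biofeedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Digital processing chain for wearable cardiorespiratory
    recordings (ECG, photoplethysmogram, nasal-thermistor respiration) and
    the downstream heart-rate-variability (HRV) biofeedback workflow:
    powerline notch and FIR band-pass filtering, multi-scale morphological
    (3M) denoising, adaptive-threshold R-peak and pulse-peak detection,
    respiration cycle segmentation, time- and frequency-domain HRV metrics
    with coherence ratio, stress-level classification, resonance-frequency
    breathing training (RFT) with a paced-breathing sweep, a synthetic
    cardiorespiratory signal generator with ground-truth annotations, and
    cohort-level summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
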