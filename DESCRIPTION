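Package: hrv3state
Title: Three-Behavioral-State Heart Rate Variability Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Point-of-care heart rate variability (HRV) analysis for a short
    Rest/Task/After behavioral paradigm: R-peak detection from single-lead ECG,
    R-R interval artifact correction and tachogram resampling at the mean heart
    rate, maximum-entropy (Burg autoregressive) spectral trends of LF and HF
    power on sliding 30-second windows, per-state averaging with a 30-second
    settling skip, the random-number-generation task index, and a 12-term
    Fisher linear discriminant separating postpartum depression, adjustment
    disorder and control profiles. Includes an integral pulse frequency
    modulation (IPFM) simulator that generates labeled synthetic cohorts with
    state-dependent autonomic modulation, so the whole pipeline is testable
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
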