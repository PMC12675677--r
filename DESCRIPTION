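Package: cape
Title: Quality-Driven Carotid-Femoral Pulse Wave Velocity Estimation from
    Multi-Channel Laser Doppler Vibrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates carotid-femoral pulse transit time (PTT) and pulse
    wave velocity (PWV) from 12-channel laser Doppler vibrometry (LDV)
    skin-displacement recordings. Displacement channels are converted to
    acceleration by zero-phase low-pass filtering and double
    differentiation; acceleration peaks (fiducial points) are detected by
    template matching with a cross-correlation threshold; carotid-femoral
    peak pairs are enumerated across channels (up to 36 per heartbeat) and
    gated by a two-level quality criterion (beat quality threshold, BQT;
    recording quality threshold, RQT) before the overall PTT, PWV and a
    beat-to-beat trend are computed. Includes Bland-Altman agreement
    analysis with guideline-based grading and a deterministic synthetic
    recording generator with ground truth for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
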