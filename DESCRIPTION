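Package: magswallow
Title: Magnetic Swallowing Detection with Cantilever Actuators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for active magnetic motion
    sensing of swallowing with body-worn permanent-magnet cantilever
    actuators and a stationary uniaxial magnetometer. Provides a dipole
    model of the tilting actuator, a synthetic raw-trace generator with
    ground truth (resonance carriers, swallow-shaped amplitude modulation,
    power hum, geomagnetic drift, sensor noise), the signal-enhancement
    chain (Butterworth highpass, IIR comb hum suppression, volt-to-tesla
    conversion, per-actuator bandpass and complex demodulation to motion
    envelopes), swallow event segmentation with pulse metrics, a
    time/frequency/wavelet feature battery, and power-normalized
    cross-correlation matrices for similarity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
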