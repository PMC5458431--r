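Package: abpkalman
Title: Kalman-Filter Denoising of Aortic Pressure Waveforms via a
    Four-Element Windkessel Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Synthesizes and denoises aortic blood pressure (ABP) waveforms.
    A four-element Windkessel lumped-parameter model of aortic circulation
    (peripheral resistance, arterial compliance, characteristic aortic
    impedance, blood inertance) is discretized by the Euler-forward method
    and embedded as the process model of a discrete linear Kalman filter
    with known aortic-flow input and scalar pressure measurement. Includes
    a synthetic-data generator for pulsatile flow and noise/artifact
    corrupted pressure, periodogram-based harmonic validation of the pulse
    waveform, estimation-error and signal-to-noise scoring, a CSV waveform
    interchange format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
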