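Package: sweeptract
Title: Exponential Sine Sweep Measurement and One-Dimensional Simulation of
    Vocal-Tract Transfer Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for transducer-independent measurement of acoustic
    transfer functions with the exponential sine sweep (ESS) technique:
    sweep synthesis with sine-squared fade envelopes, construction of the
    amplitude-modulated inverse filter, deconvolution with temporal
    separation of harmonic-distortion impulse responses, complex spectrum
    averaging and driver-reference subtraction.  Companion analytic
    predictors for closed-open tube resonances (quarter-wave modes, the
    transcendental resonance condition with frequency-dependent end
    corrections, the open-end correction coefficient for finite flanges)
    and for the antiresonance of the piriform fossae treated as
    quarter-wave side branches.  A one-dimensional plane-wave waveguide
    simulator of vocal-tract area functions with closed side branches,
    wall absorption and a radiation load reproduces the 4-5 kHz piriform
    spectral trough and the formant-repellent effect, and supports
    spectral-difference filters that remove the fossa signature from
    recorded voice.  A seeded virtual measurement rig (driver with
    polynomial distortion, tract filter, noisy probe microphone) makes the
    whole pipeline testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
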