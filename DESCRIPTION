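Package: pwsim
Title: Hemodynamic Pulse Wave Simulation and Cuffless Blood Pressure
    Monitor Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico digital twin of a hemodynamic pulse wave simulator
    (an elastic arterial phantom driven by a pulsatile pump) together with a
    model of a two-sensor cuffless blood pressure monitor that measures local
    pulse wave velocity (PWV) from pulse transit time. Implements the
    Moens-Korteweg and Bramwell-Hill relations with an exponential
    pressure-dependent wall modulus, synthesis of arterial pressure waveforms
    with reflected waves, the monitor's acquisition chain (band-pass
    filtering, 5 kHz sampling, noise), first-peak transit-time estimation,
    multiple-linear-regression calibration of measured PWV against the
    Moens-Korteweg theoretical curve, and Bland-Altman / mean-absolute-error
    agreement reporting with propagation of PWV error into blood-pressure
    error bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
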