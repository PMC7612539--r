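Package: cbpkit
Title: Central Blood Pressure Estimation from Aortic Flow with Windkessel Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the central (ascending-aortic) blood pressure
    wave from a measured aortic flow wave plus a peripheral pressure measurement.
    Implements the two- and three-element Windkessel forward models with exact
    periodic solutions, a catalogue of estimators for the cardiovascular
    parameters they require (left ventricular ejection time, outflow pressure,
    total arterial resistance and compliance, pulse wave velocity, and
    characteristic impedance), a factorial virtual-subject generator for
    validating the estimators against known ground truth, outlet Windkessel
    parameter construction for coupling to one-dimensional arterial network
    solvers, and the error-assessment battery (mean percentage error,
    Bland-Altman agreement, waveform RMSE, coefficient of determination) used
    for method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
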