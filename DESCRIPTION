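Package: acdcmotif
Title: Switch and Oscillator Dynamics of the AC-DC Gene Regulatory Motif
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of the cross-repressive transcription
    factor circuit that interprets the Sonic Hedgehog gradient in the
    ventral neural tube (Pax6, Olig2, Nkx2.2), and of the AC-DC sub-motif
    that controls its qualitative dynamics. Implements the piecewise-smooth
    (Heaviside) and graded (Hill) model variants, closed-form steady-state
    branches with existence and stability criteria, classification of the
    four qualitative regimes (multistate switch versus intermediate-signal
    oscillations), event-aware numerical integration with attractor
    detection, bifurcation scans and hysteresis sweeps over the signal
    level, spatial patterning of 1-D signal gradients into expression
    stripes including generalized n-gene circuits, parameter presets,
    random-parameter census experiments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
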