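Package: cardiolpn
Title: Lumped-Parameter-Network Cardiovascular Haemodynamics: Implicit 0D
    Simulation, Run-Time Control, and Kalman-Filter Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Zero-dimensional (lumped-parameter network) simulation of
    cardiovascular haemodynamics. Circuits of resistors, capacitors,
    inductors, ideal-diode valves, pressure/flow sources and time-varying
    elastance heart chambers are described in a plain-text netlist, assembled
    by modified nodal analysis into a differential-algebraic system and
    advanced fully implicitly with complementarity-consistent valve state
    resolution. A run-time controller framework adjusts tagged component
    parameters from the simulation state, including a myocardial oxygen
    supply/demand ("hunger") model with coronary resistance feedback and a
    post-reperfusion-syndrome scenario. A reduced-order unscented Kalman
    filter estimates circuit parameters from time-resolved pressure and flow
    observations. Presets build Windkessel, coronary and closed-loop
    circulation fixtures and synthetic noisy observation traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
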