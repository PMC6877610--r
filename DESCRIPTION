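Package: navkit
Title: Voltage-Gated Sodium Channel Models, Virtual Voltage-Clamp Protocols
    and Electrophysiological Feature Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates voltage-gated ion-channel macroscopic currents with two
    model families side by side: a parametrized Hodgkin-Huxley gating
    formalism (m3h and m3hs gate products) and a simplified five-state Markov
    kinetic scheme for the cardiac sodium channel Na_V_1.5. Six virtual
    voltage-clamp protocols (activation, deactivation, steady-state
    availability, recovery from fast and slow inactivation, and development of
    slow inactivation) are run with exact closed-form per-epoch propagation of
    the channel states, currents are fitted with the standard
    electrophysiological equations (Boltzmann, mono- and bi-exponential,
    m3h activation-decay), and the resulting features (half-activation voltage
    and slope, availability midpoint, repriming and slow-inactivation time
    constants) are compared against bundled experimental reference values for
    Na_V_1.5. A minimal single-compartment current-clamp simulator
    demonstrates spiking with either channel family.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
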