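Package: exosim
Title: Coupled Neuron-Astrocyte Simulator of Calcium-Dependent Exosomal Release
Version: 0.1.0
Authors@R: person("exosim", "maintainers", email = "exosim@example.org", role = c("aut", "cre"))
Description: Deterministic biophysical simulator of calcium-dependent exosomal
    release from neurons and astrocytes. Combines a modified Hodgkin-Huxley
    membrane with L/T-type voltage-gated calcium channel microdomains and a
    four-compartment calcium mass balance in neurons, Li-Rinzel IP3-receptor
    calcium dynamics in electrically silent astrocytes, an amyloid-beta
    modulated astrocytic calcium flux network with feedback onto the neuron,
    and a temperature extension with TRPM8 cold-channel thermodynamic gating.
    Provides fixed-step RK4 and adaptive Cash-Karp integrators, a registry of
    canonical simulation scenarios, spike and oscillation metrics, release
    accounting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
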