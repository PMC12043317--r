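Package: epvsom
Title: Gain and Stability Analysis of E-PV-SOM Cortical Circuit Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how somatostatin (SOM) interneuron modulation
    shapes stimulus gain and dynamical stability in recurrent cortical rate
    circuits with excitatory (E), parvalbumin (PV) and somatostatin (SOM)
    populations.  Implements the three-population firing-rate model with
    power-law transfer functions, closed-form construction of operating
    points from target rates, the linearised response matrix and its
    synaptic-pathway expansion, network gain and eigenvalue stability
    measures, paradoxical-response diagnostics, rate-grid scans and
    modulation vector fields, single-weight sweeps at pinned rates,
    stochastically forced simulations with frozen-noise gain estimates, and
    additive/multiplicative decomposition of tuning-curve changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
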