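Package: phglv
Title: pH-Dependent Generalized Lotka-Volterra Simulation of Nasal
    Microbial Communities
Version: 0.1.0
Authors@R:
    person("phglv", "developers", email = "phglv@example.org", role = c("aut", "cre"))
Description: Assembles stable multi-strain in silico microbial communities
    under a pH-dependent generalized Lotka-Volterra model with continuous
    dilution, and quantifies how temporal pH fluctuations (amplitude,
    frequency, waveform) perturb community composition.  Includes inference
    of interaction coefficients from supernatant assays, a synthetic strain
    panel generator, enrichment-style community assembly with stability and
    dilution-robustness filters, Bray-Curtis composition deviation
    experiments, and closed-form fast- (WKB envelope) and slow-fluctuation
    (quasi-static linear solve) limits used as built-in oracles against the
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
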