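Package: ca1place
Title: Two-Compartment Rate Model of CA1 Place-Field Formation and Stabilization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates hippocampal CA1 pyramidal neurons as two-compartment
    rate-based units with a nonlinear dendrite, gated dendrite-to-soma
    propagation, Hebbian plasticity with subtractive homeostatic
    normalization, and novelty-scheduled somatic and dendritic inhibition.
    Provides a config-driven session runner for an annular virtual track
    with Gaussian place-tuned inputs, preset experiment protocols (somatic
    current injection, place-field development, overshoot-and-return,
    noise-based stability probing, induction-driven field shifting),
    rate-map analysis utilities, and a perturbation-based place-field
    stability protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
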