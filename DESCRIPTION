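Package: tnfswitch
Title: Critical-Dose and Sensitivity Analysis of the TNF-alpha Survival/Apoptosis Switch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action ODE modeling of the TNF-alpha-driven cell-fate
    network: locates the critical stimulus dose separating survival from
    apoptosis, classifies kinetic parameters as sensitive or insensitive by
    a +/-20% perturbation protocol, correlates the resulting Boolean
    sensitivity spectrum with somatic point-mutation spectra via Hamming
    distance, and screens candidate caspase-on-NFkB feedback loops by
    injecting production or degradation terms and rescanning the
    correlation. Ships a reduced bistable toy network and a synthetic
    mutation-spectrum generator with controlled concordance for
    protocol-level validation, plus minimal SBML and tabular model I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    digest,
    jsonlite,
    stats,
    utils,
    graphics,
    xml2,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
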