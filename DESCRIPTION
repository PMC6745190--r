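Package: landesv
Title: Land-Use Change Projection and Ecosystem Service Valuation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing land-use/land-cover (LULC) change and its
    consequences for ecosystem service values. Estimates class-transition
    probability matrices from categorical rasters, projects future class
    composition with a Markov chain, allocates projected areas in space with
    a cellular-automata suitability rule (CA-Markov), and validates simulated
    maps with Cohen's kappa. Converts class areas into ecosystem service
    values with a benefit-transfer value-coefficient matrix, computes change
    rates, and quantifies the elasticity (coefficient of sensitivity) of the
    total value to coefficient perturbations. Ships published Central Asia
    value-coefficient and area tables as fixtures and a neutral-landscape
    generator so every spatial stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
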