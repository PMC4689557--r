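Package: dnaBII
Title: BI/BII Backbone Dynamics of B-DNA Duplexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of the BI/BII phosphate backbone equilibrium in B-DNA
    duplex trajectories. Classifies per-frame BI/BII states from the
    epsilon/zeta torsion difference, maps facing phosphate groups across
    complementary strands, quantifies the populations of their conformational
    combinations and tests their statistical independence, converts 31P
    chemical shifts to BII percentages, and characterises the coupling
    between backbone state combinations and inter base-pair helical
    parameters. Includes a two-state Markov generator of synthetic duplex
    torsion, pucker, helical and chemical-shift data for validating every
    analysis stage without molecular dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
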