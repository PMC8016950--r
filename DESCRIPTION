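Package: graftkit
Title: Structure-Guided Antibody Humanization by CDR Grafting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for structure-guided humanization of antibody
    Fab fragments and the quantitative assays used to validate them. Provides
    Kabat numbering of immunoglobulin V-regions with canonical insertion
    handling, extraction of Kabat-keyed Fv portions from crystal structures,
    framework-restricted Calpha superposition with Q-score ranking of human
    acceptor candidates, CDR grafting with an auditable vernier/N-terminal
    back-mutation ledger, Shrake-Rupley solvent-accessible and buried surface
    area analysis of protein-peptide interfaces with hydrogen-bond detection,
    overlapping-peptide SPOT epitope mapping with minimal-motif extraction,
    fitting of ELISA equilibrium, single-cycle SPR kinetics, saturation
    binding and Lindmo immunoreactive-fraction assays, and radiotracer
    bookkeeping (masses, adducts, decay correction, specific activity,
    biodistribution). Includes seeded synthetic-data generators for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
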