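Package: foldkin
Title: Two-State Folding Thermodynamics and Dimerization Kinetics of
    Spidroin N-Terminal Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for equilibrium and kinetic folding studies of
    small two-state protein domains, built around the spider silk protein
    (spidroin) N-terminal domain. Fits chemical and thermal equilibrium
    denaturation curves to the two-state model with linearly sloping
    baselines, performs chevron analysis of stopped-flow folding kinetics,
    fits second-order dimerization and chasing-dissociation transients to
    obtain association and dissociation rate constants and equilibrium
    dissociation constants, and quantifies Debye-Hueckel charge screening as
    the linear dependence of unfolding free energy on the square root of
    ionic strength. Includes seeded synthetic-data generators emulating CD
    and fluorescence spectroscopy for parameter-recovery validation, CSV
    readers and writers for all data dialects, and a per-homologue report
    builder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
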