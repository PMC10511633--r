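Package: protocell
Title: Stoichiometric Self-Reproduction Models of Ribosome-Centric Proto-Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds and solves coarse-grained stoichiometric models of
    self-reproducing proto-cells (SSPCMs): balance-equation systems centred on
    ribosomes, with optional amino-acid/nucleotide/lipid biosynthesis pathways,
    transcription, DNA replication, a bilayer membrane of defined geometry and
    membrane-bound energy and transport machinery. Assembles each model into a
    determined nonlinear algebraic system, solves it at an operating point,
    sweeps doubling time against ribosome number, and characterises
    doubling-time limits (closed-form asymptotes and membrane-exhaustion
    growth boundaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
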