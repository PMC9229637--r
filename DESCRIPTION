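Package: halbind
Title: Reactivity Descriptors and Binding Analysis for Halogenated Enzyme Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for halogen-substituted enzyme inhibitor series:
    conceptual-DFT global reactivity descriptors (hardness, softness, chemical
    potential, electrophilicity) from frontier-orbital energies, geometric
    profiling of noncovalent protein-ligand contacts in docked complexes
    (hydrogen bonds, pi interactions, and a protein-H-to-halogen contact
    criterion), docking free-energy to inhibition-constant conversion and
    ranking, Kabsch superposition RMSD and trajectory RMSF stability metrics,
    and descriptor-activity Pearson correlation. Includes seeded synthetic-data
    generators emulating a halogenated inhibitor series so every stage is
    testable without quantum-chemistry, docking, or molecular-dynamics runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
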