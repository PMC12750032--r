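Package: complexeval
Title: Stoichiometry-Aware Evaluation of Macromolecular Complex Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking engine for predicted macromolecular complexes.
    Reads reference and model structures (mmCIF or PDB), classifies targets
    into easy/medium/hard/ligand difficulty classes from sequence-template
    evidence, maps model chains and ligands onto the reference, and computes
    stoichiometry-aware accuracy scores: all-atom LDDT, interface LDDT,
    TM-score, LDDT-PLI, and symmetry-corrected binding-site RMSD (BiSyRMSD),
    together with mapped-chain variants, weighted ligand aggregates, pose
    success fractions at 1/2/5 Angstrom, assembly selection, and
    common-subset server comparisons. Ships a deterministic synthetic-complex
    generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
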