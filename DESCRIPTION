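Package: redock
Title: Confidence-Guided Replica-Exchange Protein-Protein Docking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for confidence-guided protein-protein docking from
    predicted complex structures. Reads PDB models carrying per-residue
    pLDDT confidence in the B-factor column, computes interface confidence
    metrics (interface residues at 8 Angstrom, Cbeta contacts at 5
    Angstrom, interface-pLDDT with an 85 gate), quantifies binding-induced
    backbone flexibility (per-residue RMSD and superposition-free LDDT),
    and runs a temperature replica-exchange rigid-body Monte Carlo docking
    engine with pluggable scoring, directed backbone perturbation of
    low-confidence segments, and energy-based decoy clustering. Docked
    models are evaluated against a reference complex with fnat, interface
    RMSD, ligand RMSD, DockQ and CAPRI quality classes. A synthetic
    fixture generator builds toy two-partner complexes with planted native
    poses so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
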