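Package: nciprofiler
Title: Residue-Centric Non-Covalent Interaction Profiling for Protein
    Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects, classifies and counts 36 operationally defined
    non-covalent interaction types (hydrogen bonds, long-range
    electrostatics, CH...O and CH...pi weak hydrogen bonds, sulfur
    contacts, orthogonal multipolar and bond-dipole interactions,
    van der Waals contacts, metal and ion coordination) around
    designated residues of protein complexes, including bridges through
    single water molecules.  Structures are typed with SYBYL atom and
    bond types plus template partial charges from a built-in residue
    dictionary, interactions are converted into grouped or individual
    descriptor count vectors, and a backbone-dependent rotamer-energy
    term can be attached.  Also provides symmetry-aware side-chain RMSD
    labelling against a reference conformation and a group-aware
    gradient-boosting evaluation harness with MCC early stopping and
    permutation importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    stats,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
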