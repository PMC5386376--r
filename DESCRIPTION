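Package: bh3struct
Title: Structural and Biophysical Analysis of Bcl-2 Family BH3-Motif Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the structural bioinformatics of pro-survival Bcl-2
    family proteins bound to BH3-motif peptides: fixed-width PDB coordinate
    input/output with deterministic altloc handling, Kabsch rigid-body
    superposition and iterative sequence-independent Calpha alignment,
    structure-based phylogenetic clustering from pairwise RMSD distance
    matrices, Shrake-Rupley solvent-accessible surface areas with buried
    interface area, hydrogen-bond, salt-bridge and BH3 hot-spot pocket
    analysis, BH3 motif scanning of protein sequences, single-site isothermal
    titration calorimetry simulation and fitting, and crystallographic
    arithmetic (unit-cell volume, Matthews coefficient, solvent content and
    unique-reflection counts). Includes parametric generators for helical
    fixtures, peptide-in-groove toy complexes, synthetic titrations and
    motif-bearing sequences used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
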