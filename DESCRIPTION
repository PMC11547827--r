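Package: pepcycle
Title: Cyclic Peptide Design and End-State Binding Energetics
Version: 0.1.0
Authors@R:
    person("pepcycle", "developers", email = "pepcycle@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for structure-based cyclic peptide design
    against protein-protein interfaces. Reads and writes two-chain PDB
    complexes and multi-model ensembles, assigns a reduced per-atom
    parameter set (charges, Lennard-Jones, solvation radii), and provides
    trajectory-style analyses (Kabsch superposition, RMSD, RMSF, interface
    residues, hydrogen-bond occupancy, dynamic cross-correlation). An
    MM-PBSA engine combines gas-phase Coulomb and Lennard-Jones cross
    terms with a finite-difference linearized Poisson-Boltzmann polar term
    and a Shrake-Rupley SASA nonpolar term, with per-residue decomposition
    and single-trajectory aggregation. On top of that sit computational
    alanine scanning with hot-spot classification, virtual point mutation
    with re-scoring, truncation-based linear peptide proposal, head-to-tail
    GP (amide) and CC (disulfide) cyclization with 3-D ring building, and
    assay-side utilities (cell-viability formula, one-site KD fitting).
    Synthetic-data generators for toy complexes, fluctuation ensembles,
    hydrogen-bond occupancy and saturation binding curves make every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
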