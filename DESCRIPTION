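Package: rotaudit
Title: Auditing Protein Side-Chain Packing by Discretized Rotamer Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing protein side-chain prediction with a
    discretized rotamer analysis. Reads and quality-filters all-atom PDB
    structures (resolution, single chain, B-factor and occupancy rules),
    computes side-chain Chi torsion angles, applies IUPAC-IUB
    symmetric-branch nomenclature corrections (ASP, GLU, PHE, TYR) and ring
    atom-name fixes, classifies each side chain into canonical
    plus/trans/minus rotamer bins (with named modes, proline C-gamma
    endo/exo and an "off" class for conformations outside all +/-30 degree
    bins), computes per-residue solvent accessible surface area by
    Shrake-Rupley sampling, and decomposes rotamer and per-Chi prediction
    errors between original and repacked structures by amino acid, solvent
    accessibility, secondary structure and protein size, including ANOVA
    with Tukey post hoc comparisons of accessibility across rotamer
    classes. A synthetic peptide generator with a ground-truth ledger and a
    mock side-chain predictor with a controllable, optionally
    accessibility-dependent confusion rate provide fully known inputs for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
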