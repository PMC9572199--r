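Package: gaginter
Title: Protein-Glycosaminoglycan Interaction Analysis from Molecular Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of receptor-glycosaminoglycan binding from multi-frame
    structural trajectories: censuses of direct intermolecular interactions
    (energy-model hydrogen bonds, hydrophobic contacts, ionic contacts),
    water- and cation-mediated bridge detection, RMSD/RMSF stability
    profiles aggregated by serum-albumin subdomain and sugar mer group,
    solvent-accessible-surface-area based binding-energy accounting with
    windowed statistics and complex ranking, and residue contact maps.
    Includes a synthetic trajectory generator that plants interactions with
    a machine-readable ground-truth ledger for validating every detector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
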