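Package: allosite
Title: Allosteric Binding-Site Analysis for Nuclear Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream analysis of allosteric binding sites on nuclear
    receptor ligand-binding domains: selection of site residues around a
    cocrystallized ligand and group-aware sequence-conservation scoring
    across receptors; conversion of cosolvent-probe trajectories into
    bulk-normalized density grids with isovalue hotspot extraction;
    DBSCAN clustering of water positions from simulation snapshots and
    merged crystal structures into hydration sites with occupancy
    filtering and a distance-threshold consensus; Kabsch superposition,
    medoid representative selection and per-residue heavy-atom RMSD to
    quantify probe-induced conformational adaptation; and docking-score
    enrichment statistics (ROC AUC, score shifts, pose RMSD). Includes
    seeded synthetic-data generators with known ground truth standing in
    for the molecular dynamics and docking engines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    seqinr,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
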