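Package: rotadimer
Title: Sidechain Rotamer and Dimer-Interface Analysis of Receptor MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of G
    protein-coupled receptors and their dimers. Reads multi-MODEL PDB
    trajectories, maps residues to Ballesteros-Weinstein generic numbers,
    computes backbone and ligand RMSD traces with Kabsch superposition,
    classifies chi1 sidechain rotamers into cis/trans pseudo-states at a
    240-degree threshold, fingerprints protein-ligand close contacts and
    partitions them across ligands, characterizes homodimer interfaces
    (inter-protomer distances, hydrogen-bond occupancy, a simplified
    screened-Coulomb plus Lennard-Jones interaction energy) and performs
    computational alanine scanning. Ships a synthetic trajectory generator
    with exact ground truth so every analysis stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
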