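Package: globinmelt
Title: Post-Simulation Analysis of Globin Thermal Unfolding Trajectories
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing thermal unfolding trajectories of
    holomyoglobin and related globins exported as multi-model PDB files.
    Implements Kabsch-Sander (DSSP-style) secondary-structure assignment
    from backbone hydrogen-bond electrostatics, a structure-to-ellipticity
    model linking helix content to the mean residue ellipticity at 222 nm
    (forward prediction and exact inversion with helix-truncation,
    helix-number and random-coil corrections), per-frame structural
    observables (optimal-superposition RMSD, radius of gyration,
    Shrake-Rupley solvent-accessible surface area, contact maps, heme
    iron to proximal-histidine distance), heme-loss detection, and
    identification of unfolding intermediates by k-means clustering with
    silhouette validation. A synthetic-trajectory generator with full
    ground truth supports end-to-end testing without any deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    cluster,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
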