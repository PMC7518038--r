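Package: PoseSAR
Title: SAR-Congruency Selection of Protein-Ligand Docking Poses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects protein-ligand binding hypotheses from docking-pose
    ensembles by congruency with structure-activity relationships (SAR).
    Given docking poses of a reference ligand from a congeneric series,
    the package derivatizes every pose in 3D into the full analog series,
    estimates binding energies with a molecular-mechanics scoring function
    and restrained local minimization, and ranks poses by the SAR
    congruency coefficient (the per-pose Pearson correlation between
    predicted binding energies and measured potencies), with leave-one-out
    q2, Y-scrambling and empirical p-values for statistical validation.
    Pose-space analytics (scaffold RMSD matrices, classical
    multidimensional scaling, binding-mode assignment) and structural
    interaction fingerprints (SIFt) characterize the selected binding
    modes. A synthetic toy-pocket generator with a planted true pose makes
    the whole protocol testable end to end. Ships the pyrazoloquinolinone
    (PQ) potency table for the GABA-A receptor alpha1+/beta3- interface
    used throughout the examples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    ChemmineR,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
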