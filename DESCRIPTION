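Package: stereoscreen
Title: Enantioselectivity and Reactivity Screening from Docked Pose Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: In-silico functional screening of flavin-dependent monooxygenase
    libraries downstream of structure prediction and docking. Clusters docked
    ligand pose ensembles with a deterministic leader algorithm, calls per-cluster
    R/S enantioselectivity from the orientation of the ligand ring plane relative
    to the FAD cofactor, and combines clusters into a Boltzmann-weighted R
    fraction. Fits a logistic reactivity classifier on five docking-derived
    descriptors, builds binding-site and second-shell sequence feature matrices
    from multiple sequence alignments, trains cross-validated tree-ensemble
    sequence-function models, and ranks key residues by consensus SHAP
    importance with per-amino-acid dependence profiles. Ships synthetic-data
    generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
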