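Package: usrml
Title: Machine-Learning-Augmented Ultrafast Shape Recognition Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Ligand-based virtual screening with Ultrafast Shape Recognition
    (USR) and ElectroShape 4D/5D moment descriptors. Computes
    rotation-invariant shape descriptors from 3D conformers, screens compound
    libraries with the classical inverse-Manhattan similarity or with
    per-target machine-learning scoring models (Gaussian mixture models,
    isolation forests, single-hidden-layer neural networks) trained on
    descriptors, and evaluates retrospective screens with enrichment factors,
    ROC AUC, improvement ratios and Wilcoxon rank-sum comparisons, including
    a training-set fraction sweep. Conformer generation (ETKDG, MMFF94
    single-point energies and charges, Crippen atomic logP) is delegated to a
    bundled RDKit helper; synthetic point-cloud and descriptor-population
    generators make the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ChemmineR,
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with RDKit for conformer generation and
    SMILES standardization; OpenBabel CLI for V3000 SDF conversion (both
    optional, only needed by the chemistry-facing functions).
Config/testthat/edition: 3
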