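Package: SwitchScore
Title: Dynamics Scoring and Meta-Classification of Switch-Regulated
    GTPase Variant Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for scoring conformational-ensemble differences across
    mutational landscapes of switch-regulated GTPases such as KRAS.
    Provides trajectory input (PDB/DCD/multi-model PDB), region-aware
    Kabsch superposition, per-residue mobility (RMSF) and SSR profile
    statistics, RMSD distributions against reference conformations,
    principal-component free-energy landscapes with two-well occupancy
    ratios, literature-derived residue-pair distance monitors with
    sigma-from-wild-type scoring, simplified protein-ligand nonbonded
    interaction energies, wild-type-standardized three-way and nine-group
    classification into meta-classes, k-means group signatures, 2D
    embeddings, and melting-temperature analysis of nanoDSF-style thermal
    unfolding curves (Tm, dTm, ddTm and activation-stability ddTm*).
    A synthetic-ensemble generator with planted ground truth makes every
    stage testable without molecular-dynamics output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'SwitchScore-package.R'
    'score-table.R'
    'classify.R'
    'cluster.R'
    'trajectory-ensemble.R'
    'energy.R'
    'fel.R'
    'region-map.R'
    'io.R'
    'monitors.R'
    'pca.R'
    'synthetic-other.R'
    'thermostability.R'
    'superpose.R'
    'rmsd.R'
    'rmsf.R'
    'synthetic-ensemble.R'
    'pipeline.R'
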