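Package: StressENM
Title: Elastic Network Stress Model of Site-Specific Protein Evolution
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds coarse-grained elastic network models (parameter-free
    anisotropic network model and cutoff anisotropic network model) from
    protein C-alpha coordinates, computes site-specific dynamical
    flexibility (mean square fluctuations from the pseudo-inverse of the
    Hessian) and mean local mutational stress (the expected elastic energy
    stored by random rest-length perturbations of a site's springs), and
    compares a mechanistic stress model of site-specific evolutionary
    rates against an empirical flexibility model using linear fits, AIC,
    AIC weights, Pearson and partial correlations, and binned
    rate-versus-predictor profiles. Includes deterministic synthetic
    structure generators so the full pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
biocViews: StructuralBioinformatics, Proteomics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'StressENM-package.R'
    'comparison.R'
    'enm.R'
    'pipeline.R'
    'predictors.R'
    'stress.R'
    'structure-io.R'
    'utils.R'
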