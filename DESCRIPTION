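Package: ecoassembly
Title: Null-Model Inference of Community Assembly Processes Across Habitat Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the ecological processes that assemble microbial
    communities (selection, dispersal limitation, homogenizing dispersal and
    drift) from phylogenetic and compositional turnover null models. Implements
    abundance-weighted MNTD/NTI and betaMNTD/betaNTI with taxa-shuffle nulls,
    the Raup-Crick null model on Bray-Curtis dissimilarity, classification of
    pairwise turnover into assembly processes, scale-restricted null pools for
    nested sampling designs (region, site, plot, host plant), chi-square tests
    of process proportions across scales, and an environmental/spatial driver
    analysis (PCNM, PCA, PCoA, distance-based RDA with permutation forward
    selection, Spearman correlations with Bonferroni adjustment). Ships a
    synthetic-data generator that simulates dated phylogenies, nested sampling
    designs and OTU tables under known assembly regimes so every stage of the
    pipeline can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'assembly.R'
    'cli.R'
    'drivers.R'
    'ecoassembly-package.R'
    'io.R'
    'phylo.R'
    'raupcrick.R'
    'synth.R'
    'utils.R'
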