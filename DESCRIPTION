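Package: chemscreen
Title: Analysis of Arrayed Chemical-Genomic Colony Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for quantitative analysis of arrayed chemical-genomic
    screens in bacteria: parsing of colony quantification tables (Iris-style
    size/opacity/circularity output), robust quartic plate-surface
    normalization, power transformation and between-plate variance
    normalization, replicate-aware fitness scoring with per-condition
    empirical false-discovery-rate phenotype calling, gene-gene correlation
    networks with permutation-FDR significance cutoffs, average-linkage
    hierarchical clustering with Cluster 3.0 compatible output, and gene-set
    enrichment analysis over functional categories. Includes a synthetic
    screen generator with planted plate-surface artifacts and gene-condition
    effects for end-to-end validation, and models for downstream assays:
    minimal inhibitory concentration calling from broth microdilution,
    exponential-decay fits of translation-inhibition kinetics with AICc model
    selection, and the quadratic ligand-depletion binding isotherm.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
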