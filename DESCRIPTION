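Package: adaptscape
Title: Landscape Genomics of Climate Adaptedness and Genomic-Informed Seed Sourcing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for landscape-genomic analyses of climate adaptedness in trees
    and other sessile species: post-calling SNP quality control (depth masking,
    minor-allele-frequency and missingness filters, linkage-disequilibrium
    pruning, modal imputation), climate-variable collinearity pruning and
    scenario management, population-structure diagnostics (PCA, Mantel and
    partial Mantel tests), partial redundancy analysis variance partitioning and
    candidate-adaptive-SNP detection with genomic-inflation-factor calibration,
    three genomic-offset engines (gradient forest, redundancy-analysis adaptive
    index, generalized dissimilarity models) with an adaptedness index
    (-1 x offset), donor-recipient seed-transfer analysis (forward and reverse
    adaptedness, seed-source priority, radius-restricted donor search),
    cross-method concordance (Procrustes, Spearman) and protection-status nested
    ANOVA, plus a synthetic-landscape generator that emulates clinal adaptive
    loci on a spatially autocorrelated neutral background for fully reproducible
    desk-scale studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    pracma,
    randomForest,
    stats,
    tools,
    utils,
    vcfR,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
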