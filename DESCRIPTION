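Package: poolscape
Title: Pool-Seq Landscape Genomics for Contrasting Neutral and Adaptive
    Variation Between Forest Stand Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing neutral and adaptive genetic variation
    between population sets from pooled sequencing (Pool-Seq) data, motivated
    by contrasts of old-growth and planted conifer stands along climate
    gradients. Provides SNP filtering and allele-frequency estimation from
    pooled variant calls (VCF or sync format), the Hivert et al. (2018)
    ANOVA pairwise FST estimator for pools, outgroup f3 shared-drift
    statistics with block-jackknife errors, per-stand diversity summaries,
    gene-environment outlier detection by a Monte-Carlo correlation null and
    by latent-factor-corrected regression with genomic-control calibration,
    isolation-by-distance and isolation-by-environment (partial) Mantel
    tests, and the risk of non-adaptedness (RONA) under a projected future
    climate. A synthetic-landscape generator with known adaptive clines,
    provenance decoupling and latent neutral structure provides ground truth
    for every inference stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
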