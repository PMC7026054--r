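Package: eqtlwm
Title: LD-Adjusted eQTL Scores and White-Matter Microstructure Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Constructs per-individual genetic proxies of gene expression
    (eQTL scores) from expression quantitative trait locus summary
    statistics, adjusting effect-size vectors for linkage disequilibrium
    with the Moore-Penrose generalized inverse of a reference-panel SNP
    correlation matrix, and tests the scores against diffusion-MRI white
    matter phenotypes. Includes allele harmonization, cross-study score
    de-duplication by best SNP p-value, PCA-derived global and
    tract-category latent phenotypes, hemisphere-aware linear mixed models
    for bilateral tracts, incremental variance explained, two-family
    Benjamini-Hochberg FDR correction, and a block-LD synthetic-data
    generator with planted effects so the whole pipeline is testable end
    to end with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
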