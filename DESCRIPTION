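Package: pigsnp
Title: Population Genomics of SNP-Chip Genotypes: Diversity, Selection
    Scans and Haplotype Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for population-genomic analysis of
    dense diploid SNP-chip genotypes across many populations (breeds).
    Implements per-population diversity statistics (nucleotide diversity,
    observed heterozygosity, proportion of polymorphic markers), per-SNP and
    pairwise Weir-Cockerham and Hudson Fst, identity-by-state and Nei
    standard genetic distances with neighbor-joining trees, PLINK-style
    sliding-window runs-of-homozygosity calling, linkage-disequilibrium
    decay curves with the r2 = 0.3 extent statistic, the locus-specific
    branch length (LSBL) three-population selection scan with empirical
    thresholding and gene-proximity annotation, haplotype extraction with
    minimum-spanning-tree networks, shared fixed-haplotype block detection,
    tag-SNP selection and carrier-versus-noncarrier trait association.
    A Balding-Nichols simulator with planted selection sweeps, ROH tracts,
    founder-haplotype blocks and quantitative traits makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    igraph,
    rtracklayer,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
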