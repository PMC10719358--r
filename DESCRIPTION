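Package: svpopscan
Title: Population-Scale Structural-Variant Merging, Differentiation Scans
    and Phenotype Bridging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population analyses of structural variants (SVs)
    called from long-read sequencing: multi-caller within-sample consensus,
    nonredundant cross-sample merging by breakpoint distance and reciprocal
    overlap, cohort landscape statistics (carrier-frequency spectrum,
    saturation curves, Hardy-Weinberg tests, power-law fits of the
    frequency spectrum, presence/absence PCA and clustering), a
    Weir-Cockerham F_ST selection scan with population-specificity filters,
    kernel-density SV hotspot detection with a permutation null, linkage
    disequilibrium bridging of SVs to phenotypes through GWAS-catalog SNPs,
    and regulatory-element overlap with breakpoint padding. A fully
    parameterised two-population cohort simulator (Balding-Nichols
    differentiation, per-caller noise models, LD-tagged SNPs, annotation
    tracks) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils,
    ape,
    vcfR,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    igraph,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
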