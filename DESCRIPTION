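Package: mlgtools
Title: Multilocus Genotype Collapsing and Redundancy Assessment for
    Clonal Germplasm Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects genetically redundant accessions in clonally
    propagated germplasm collections genotyped with codominant SNP and
    dominant presence/absence markers. Provides marker- and sample-level
    quality filtering cascades, identity-by-state and Jaccard pairwise
    distances with pairwise-complete missing-data handling, calibration
    of a minimum genetic-distance threshold from technical and biological
    replicate pairs, agglomerative collapsing of samples into multilocus
    genotypes (MLGs) with threshold sweeps, hierarchical clustering with
    Newick export, cross-marker partition concordance, per-region
    redundancy summaries, and passport/characterization descriptor
    concordance scoring. A synthetic-collection generator with a
    three-level replicate hierarchy and ground truth supports end-to-end
    validation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
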