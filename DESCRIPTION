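Package: bcx
Title: Biocultural Complexity from Mutual Information on Species-by-Culture Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the structure of a biocultural ensemble from a table of
    interaction counts between biological taxa and cultural groups. Computes the
    mutual information between taxa and groups (in bits), the biocultural
    complexity (its exponential: the effective number of biocultural units),
    per-taxon specificity and per-group specialization indices, and within-group
    Shannon diversity. Provides bootstrap bias correction, standard errors and
    basic (reverse-percentile) confidence intervals for every index, a Monte
    Carlo chi-square test of taxon-by-group association with both margins fixed,
    a synthetic-ensemble simulator with tunable stratification, and a small
    command-line interface for table analysis and report rendering.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
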