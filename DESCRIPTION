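Package: alleleshare
Title: Allele-Sharing Estimation of Inbreeding, Kinship and Population
    Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates descent measures - individual inbreeding, pairwise
    kinship (coancestry), and population-level F-statistics - from SNP
    dosage data using allele-sharing statistics, always relative to an
    explicit reference set of allele pairs. Ratio-of-averages combination
    over variants gives estimates whose rankings are invariant to the
    choice of reference set. Includes the classical comparator estimators
    (dosage-centered "standard" kinship, KING-robust, Li-Horvitz, Nei 1973
    and 1986 FST, Weir-Cockerham 1984 ANOVA, Hudson allelic FST, and the
    f2/f3/f4 admixture statistics), path-counting pedigree coancestry,
    gene-dropping and Balding-Nichols population simulators for
    parameter-recovery testing, and block-bootstrap confidence intervals.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
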