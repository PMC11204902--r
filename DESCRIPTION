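Package: prscad
Title: Polygenic Score Harmonization and Case-Control Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Replication toolkit for published polygenic scores in a
    case-control genotype panel. Harmonizes PGS-Catalog-style scoring files
    against a target dosage panel (allele switching with effect reversal,
    strand flips, linkage-disequilibrium proxy substitution), computes
    additive dosage-weighted polygenic scores, applies array-era quality
    control (call rates, heterozygosity outliers, Hardy-Weinberg exact
    test), selects principal components of population structure by the
    Tracy-Widom test, and quantifies each score's incremental contribution
    to disease discrimination via nested logistic models and the Nagelkerke
    pseudo-R-squared difference with Bonferroni correction. Includes a fully
    seeded synthetic-cohort generator (Balding-Nichols structure, block LD,
    calibrated covariates, planted score effects) so the whole pipeline is
    testable without cohort access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
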