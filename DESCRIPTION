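Package: grsQTL
Title: Combinatorial Genetic Risk Score eQTL Scanning
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects joint (epistatic) effects of disease-associated genetic
    variants on gene expression by combining genetic risk scores (GRS) with
    eQTL mapping. All subsets of a weighted variant panel are enumerated; for
    each subset a normalized GRS stratifies individuals into low- and
    high-risk quantile groups, and expression of every gene is compared
    between groups by covariate-adjusted linear regression with
    Benjamini-Hochberg control of the false discovery rate across each test
    series. Includes a synthetic cohort generator with planted single-variant
    and joint additive effects, readers and writers for genotype (VCF/TSV),
    expression, covariate and variant-weight tables, risk-group size
    calibration against known eGenes, and reporting of eGene summaries,
    variant contribution profiles, combination trees and cross-dataset
    replication.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    data.table,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
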