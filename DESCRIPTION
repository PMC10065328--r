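Package: epiblup
Title: Epistasis-Aware Genomic Prediction Across Years with Selected
    Pairwise Interactions
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genomic prediction of phenotypes for fully homozygous
    (doubled-haploid) lines using additive (GBLUP) and epistatic
    relationship kernels built from all pairwise marker combinations
    (ERRBLUP) or from a subset of interactions selected by estimated
    effect variance (sERRBLUP).  Includes univariate and bivariate
    (two-year) REML mixed models with an initialization and
    fixed-component fallback protocol, a cross-validation evaluation
    pipeline reporting predictive ability and prediction accuracy,
    variance-inflation-factor LD pruning, readers for VCF, PLINK raw
    and delimited genotype tables, and a doubled-haploid simulator
    with block-structured linkage disequilibrium for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
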