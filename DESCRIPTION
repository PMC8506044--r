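Package: rnatmb
Title: Tumor Mutation Burden Estimation from Tumor-Only RNA-Seq Variant Callsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates tumor mutation burden (TMB, somatic mutations per
    megabase of analyzed exonic sequence) from tumor-only RNA-seq variant
    callsets produced by a Mutect2-style caller, without a matched normal
    sample. Germline and artifact variants are removed either by deterministic
    rules (caller filter labels, ExAC population allele frequency, dbSNP
    membership) or by a gradient-boosted classifier trained on variants
    labeled against a matched whole-exome callset. Includes TMB computation
    against an explicit exonic region denominator, concordance evaluation of
    RNA-seq TMB against WES TMB (correlations and ROC AUC at clinical
    thresholds), and a synthetic paired-cohort simulator with known truth
    covering FFPE C>T artifacts, RNA-specific noise, and depth-dependent
    variant detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
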