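Package: prsvol
Title: Polygenic Risk Scoring and Subcortical Volume Association
Version: 1.0.0
Authors@R: person("prsvol", "developers", email = "prsvol@example.com",
    role = c("aut", "cre"))
Description: Tools for associating polygenic (genetic) risk scores with
    quantitative brain phenotypes in a target cohort: reading and
    harmonising GWAS summary statistics against genotype dosages,
    minor-allele-frequency filtering, greedy P-value-ordered LD clumping,
    log-odds-weighted scoring at multiple P-value thresholds,
    covariate-adjusted regression reporting incremental variance explained
    with permutation-based significance, and a Fisher-z power calculator
    for correlations. Includes a synthetic-data generator that emulates a
    cross-disorder (shared versus disorder-specific) genetic architecture
    with LD-blocked genotypes, four coupled summary-statistics sets and
    covariate-laden volume phenotypes, so the whole pipeline is testable
    without access to individual-level cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    optparse,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
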