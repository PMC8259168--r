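Package: metaboQTL
Title: Integrative Metabolite QTL Mapping, Colocalization and Mendelian
    Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating blood metabolomics, genotypes and immune
    phenotypes in population cohorts: covariate-adjusted Spearman association
    screening with Benjamini-Hochberg FDR, multi-step explained-variance
    estimation, metabolite-QTL scanning with Bonferroni thresholds and
    LD-based locus clumping, permutation-based functional-class enrichment,
    Bayesian colocalization via Wakefield approximate Bayes factors,
    two-sample Mendelian randomization (inverse-variance weighted, weighted
    median, simple and weighted mode), and cross-validated elastic-net
    prediction of stimulated cytokine responses. Includes a fully seeded
    synthetic-data generator emulating LD-blocked genotypes, log-normal
    metabolite features with planted genetic and covariate effects, cytokine
    responses, and paired GWAS summary statistics for shared-causal,
    distinct-causal and null scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
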