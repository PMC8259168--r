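# metaboQTL

Integrative analysis of blood metabolomics, genotypes and immune
phenotypes, for researchers asking how much of the inter-individual
variation in circulating metabolites and cytokine responses is genetic,
which loci drive it, and whether a metabolite is *causally* linked to
disease.

The package implements, as tested and reusable R functions, the full
statistical chain of a multi-omics cohort study:

1. **QC and preprocessing** — log10 transformation, PCA-based sample
   outlier flagging (|PC score| > 4 SD on PC1 or PC2), Shapiro–Wilk
   normality reporting, variant filtering at MAF ≥ 0.05 and exact-test
   HWE p ≥ 1e-4, covariate residualization.
2. **Association screening** — covariate-adjusted Spearman correlation
   between feature families with Benjamini–Hochberg FDR per scan, plus
   host-factor scans and complete-linkage clustering of correlation
   matrices.
3. **Explained variance** — association-screened, collinearity-pruned
   multivariate OLS reporting the total model adjusted
   R² = 1 − (1 − R²)(n − 1)/(n − p − 1).
4. **mQTL mapping** — additive linear model per SNP–feature pair with
   covariates (Frisch–Waugh fast path), per-platform Bonferroni
   thresholds (5e-8 / m features), greedy LD clumping (r² > 0.1, 1 Mb
   window), and per-metabolite genetic variance.
5. **Enrichment** — permutation-based functional-class enrichment with
   add-one empirical p (floor 1/1001 at 1000 permutations) and
   Fisher-exact catalog overlap against a height-catalog reference.
6. **Colocalization** — Wakefield approximate Bayes factors,
   log ABF = ½[log(V/(V+W)) + z²·W/(V+W)], combined into posterior
   probabilities of hypotheses H0–H4 with priors p1 = p2 = 1e-4,
   p12 = 1e-5.
7. **Mendelian randomization** — instrument harmonization (allele
   alignment, palindromic-SNP removal, LD pruning at r² < 0.01), Wald
   ratios β_Y/β_X, and four estimators: inverse-variance weighted,
   weighted median, simple and weighted mode, plus Cochran's Q.
8. **Prediction** — paired 10 × 2-fold cross-validated elastic nets
   testing whether metabolites add out-of-sample predictive power for
   stimulated cytokine responses beyond SNPs.

A fully seeded synthetic-data module generates LD-blocked genotypes,
log-normal metabolomes with planted genetic/covariate variance fractions,
cytokine responses, and paired exposure/outcome GWAS summary statistics
under shared-causal, distinct-causal and null scenarios — with a truth
ledger, so every estimator is validated by parameter recovery.

## Worked example

The demo command simulates a cohort, runs QC → correlation → mQTL →
enrichment → colocalization → MR end-to-end, and surfaces the planted
causal chain (a metabolite under strong genetic control whose locus is
shared with a disease trait):

```r
library(metaboQTL)
res <- runDemo(seed = 1)

res$coloc_pp4
#> [1] 1
round(res$mr_estimates, 4)
#>             ivw weighted_median     simple_mode   weighted_mode
#>         -0.0754         -0.0715         -0.0661         -0.0660
res$planted_theta
#> [1] -0.07
round(res$exposure_genetic_variance, 3)
#> [1] 0.21
```

Reading: the colocalization posterior for a shared causal variant
(PP(H4) = 1.00) confirms the exposure metabolite and the outcome trait
share their association signal; all four MR estimators agree on a
negative causal effect near the planted θ = −0.07; and the lead SNPs
recover about two thirds of the metabolite's planted 30% genetic
variance at the demo's modest n = 600 (at n = 5000 the recovery is within
±0.02). Individual stages are plain functions:

```r
g   <- simulateGenotypes(2000, list(list(nSnps = 10,
                                         mafRange = c(0.1, 0.5),
                                         rho = 0.8)), seed = 1)
g
#> GenotypeMatrix: 2000 samples x 10 SNPs
#>   chromosomes: chr1
#>   MAF range: [0.102, 0.396]
bonferroniThreshold(5e-8, 231)   # targeted-platform mQTL threshold
#> [1] 2.164502e-10
```

A YAML-driven run (`runPipeline("config.yaml")`) writes every stage
output plus a manifest (seed, thresholds, per-stage row counts) under the
configured output directory; `defaultConfig()` lists all keys. A thin
shell wrapper lives at `inst/scripts/run_pipeline.R`.

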