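---
title: "Methods: integrating blood metabolomics, genotypes and immune phenotypes"
author: "metaboQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating blood metabolomics, genotypes and immune phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboQTL)
```

# Overview

metaboQTL implements an integrated analysis of circulating metabolites,
genotypes and immune phenotypes in a population cohort: covariate-adjusted
association screening, explained-variance estimation, metabolite-QTL (mQTL)
mapping with locus clumping, functional-class enrichment, Bayesian
colocalization, two-sample Mendelian randomization (MR), and a
cross-validated elastic-net comparison asking whether metabolite levels add
predictive power for stimulated cytokine responses beyond genetics. Every
stage is exercised end-to-end on a synthetic-data generator whose planted
parameters are known, so each estimator can be validated by recovery rather
than by fiat.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the points where the design was
genuinely open and a decision had to be made.

# Data model and preprocessing

**Containers.** `GenotypeMatrix` holds a samples x SNPs dosage matrix
(alternate-allele counts in [0, 2], missing allowed) with per-SNP metadata
(id, chromosome, 1-based position, ref/alt alleles, MAF computed on
non-missing dosages). `FeatureMatrix` holds a samples x features matrix
with a platform tag (targeted NMR "BM", flow-injection "GM", untargeted
"UM", plus cytokine and cell-count panels). `SummaryStats` holds one
trait's per-SNP GWAS effect table (effect allele, other allele, EAF, beta,
SE, p, N); a stored p that disagrees with the two-sided normal p implied
by beta/SE by more than 10% relative tolerance triggers a warning, not an
error, because public summary files are often rounded.

**Genotype QC.** `filterVariants()` removes SNPs with MAF < 0.05 or an
exact-test Hardy-Weinberg p < 1e-4. The threshold pair is the conventional
chip-QC setting; the exact test (conditional distribution of the
heterozygote count given allele counts) is used because dosages at toy
scale are effectively hard calls — they are rounded to {0, 1, 2} for the
test only, never persisted as rounded.

**Metabolite QC.** Metabolite values are strictly positive and right-skewed,
so analysis happens on the log10 scale (`logTransform()`; zeros are
replaced per feature by half its smallest positive value under the
`half_min` policy). Sample outliers are flagged by PCA
(`pcaOutliers()`): features are z-scored (a per-feature standardization is
adopted; leaving features on raw scale would let high-variance features
dominate PC1), missing entries are mean-imputed for the decomposition only,
and a sample is flagged when its PC1 *or* PC2 score lies more than 4 SD
from that component's mean. The OR reading is the conservative QC
interpretation and matches the behaviour of removing a single extreme
sample. `normalityReport()` tabulates per-feature Shapiro-Wilk statistics;
it is a report, not a filter.

**Covariates.** Age (years, untransformed), sex and contraceptive use
(0/1), optionally cell-population abundances. "Correcting for" covariates
is implemented throughout as residualize-then-analyse: per-feature OLS on
the covariates with intercept, complete-case per feature, residuals carried
forward. Rank-deficient covariate sets abort with the collinear columns
named.

# Association screening

`adjustedSpearmanScan()` residualizes both feature families on the
covariates and computes Spearman's rho on the residuals, with average ranks
for ties and the t-approximation p-value
\(t = \rho\sqrt{(n-2)/(1-\rho^2)}\) (used for n > 10; pairs with fewer
than 10 complete observations are reported with undefined p).
Benjamini-Hochberg adjustment is applied across the full a x b grid of one
call — one FDR family per scan, mirroring per-category association tables.
Residualize-then-Spearman (rather than a rank-based partial correlation)
is a deliberate choice: it is the simplest mechanism consistent with
"correcting for" covariates, and it reduces exactly to plain Spearman when
the covariates are constant.

`hostFactorScan()` applies the same machinery per host factor (sex, age,
BMI, contraceptive use), BH-adjusted within factor, and summarizes the
fraction of features significant at FDR 0.05 and the sign split among
discoveries. `clusterCorrelationMatrix()` orders correlation heatmaps by
complete-linkage agglomerative clustering on Euclidean distances between
rho-vectors; undefined correlations are imputed as zero for the distance
computation (and logged).

# Explained variance

`explainVariance()` implements the multi-step procedure: (1) select
candidates marginally associated with the response at adjusted-Spearman
p < 0.001 for metabolite candidates (0.05 for other feature classes);
(2) residualize response and candidates on covariates; (3) greedily drop
collinear candidates at pairwise |r| > 0.9, keeping the one with the
smaller marginal p; (4) fit a multivariate OLS and report
\(\bar R^2 = 1 - (1-R^2)(n-1)/(n-p-1)\).

Three open points were pinned here. The collinearity criterion (pairwise
|r| > 0.9, greedy, best-p-first) is one defensible reading of "removing
collinearity"; it is configurable and logged. Negative adjusted R-squared
is clamped to zero for reporting — explained variance cannot be negative —
with the raw value retained. Selection and fitting intentionally share the
same data, as in the original procedure; the optimism this induces is real
and is bounded empirically by the null simulation in the test suite
(200 pure-noise candidates at n = 500 with the 0.001 selection threshold
yield clamped adjusted R-squared below 0.05). With the looser 0.05
threshold the selection optimism alone pushes adjusted R-squared near
0.05-0.10 — a good reason the metabolite screen uses 0.001.

# mQTL mapping

`qtlScan()` fits the additive model feature ~ dosage + covariates for
every SNP-feature pair. For speed both sides are residualized on the
covariates once; by Frisch-Waugh the simple-regression slope on residuals
equals the full-model SNP coefficient, and t/p are computed at the
full-model residual degrees of freedom n - k - 2. The fast path is checked
against full OLS to 1e-6 in the tests. Missing dosages are mean-imputed at
analysis time only.

Significance uses `bonferroniThreshold(5e-8, mFeatures)` — the genome-wide
level divided by the number of features on the platform (231 targeted
features give 2.16e-10; 1589 give 3.15e-11; 8614 give 5.80e-12; all
10434 together give 4.8e-12). `clumpLoci()` reduces significant records to
loci greedily: the unassigned SNP with the smallest p leads, absorbing
unassigned SNPs on the same chromosome within 1 Mb whose squared dosage
correlation with the lead exceeds 0.1. The 1 Mb window is a package
decision (an unbounded window is quadratic and biologically unmotivated);
r-squared of dosages is used as the LD statistic, consistent with its use
for MR instrument pruning. `geneticVariance()` reports the covariate-
adjusted, clamped adjusted R-squared of a feature on its lead SNPs.

# Enrichment

`annotateSnps()` assigns functional classes by positional overlap
(1-based inclusive; BED input is shifted on ingest) with the priority
exonic > 5'UTR > 3'UTR > intronic when intervals overlap, "intergenic"
otherwise, and assigns genes within a 10-kb window around the gene body.
`permutationEnrichment()` draws 1000 same-sized SNP sets from the
non-significant background and reports the add-one empirical p
\((1 + \#\{null \ge obs\})/(n_{perm}+1)\), which can never be zero and
floors at 1/1001 — matching the "P < 0.001" reporting convention.
`catalogOverlapFisher()` tests whether a trait catalog overlaps the mQTL
set more than a height catalog does (height as the null reference), via a
one-sided Fisher exact test on
[[|mqtl n trait|, |trait \\ mqtl|], [|mqtl n height|, |height \\ mqtl|]].
The 2x2 construction is pinned here because the verbal description admits
more than one table; it is logged with the result.

# Colocalization

Per SNP and trait, the Wakefield log approximate Bayes factor is
\(\tfrac12[\log\frac{V}{V+W} + z^2\frac{W}{V+W}]\) with \(V = se^2\),
\(z = \beta/se\) and prior effect variance \(W\). Prior SDs default to
0.15 for quantitative traits and 0.2 (log-odds) for case-control traits —
the conventional choices, configurable. Under the one-causal-variant-per-
trait assumption, `colocPosteriors()` combines per-SNP ABFs into posterior
probabilities of H0 (no association), H1/H2 (one trait only), H3 (two
distinct causal variants) and H4 (one shared causal variant) with priors
p1 = p2 = 1e-4, p12 = 1e-5. All sums run in log space; the H3 mass
\(L_1 L_2 - L_{12}\) is clamped at zero if floating-point cancellation
drives it negative (logged), and a single-SNP region has PP(H3) = 0
structurally. The closed form is verified against explicit enumeration
over all single- and ordered two-SNP causal configurations to 1e-9.

# Mendelian randomization

`harmonizeAndSelect()` builds the instrument table: exposure p < 5e-8,
greedy LD pruning at r-squared < 0.01 (by ascending exposure p, against a
genotype reference panel), outcome effect alleles aligned to the exposure
(sign and EAF flipped when swapped), and palindromic A/T-C/G SNPs dropped
when the exposure EAF lies in [0.42, 0.58], where strand cannot be
resolved from frequency. Per-instrument Wald ratios
\(\hat\theta_j = \beta_Y/\beta_X\) carry the first-order SE
\(\sigma_Y/|\beta_X|\) (the standard approximation; a second-order variant
would add a \(\sigma_X\) term and matters only for weak instruments, which
the p-threshold excludes).

Estimators in `mrEstimate()`:

* **IVW**: \(\hat\theta = \sum w_j\hat\theta_j/\sum w_j\),
  \(se = \sqrt{1/\sum w_j}\) with \(w_j = 1/\sigma_j^2\) — fixed-effect by
  default, with an optional multiplicative random-effects inflation by
  \(\sqrt{Q/df}\) when \(Q/df > 1\).
* **Weighted median**: the interpolated 50% point of the ordered ratios
  under normalized cumulative weights; SE by seeded parametric bootstrap
  (1000 draws of \(\beta_X, \beta_Y\) from their sampling distributions).
* **Simple / weighted mode**: the argmax of a Gaussian-kernel density over
  the ratios (unweighted / inverse-variance weighted), bandwidth
  \(\varphi \cdot 1.4826\,\mathrm{MAD} \cdot n^{-1/5}\) with \(\varphi = 1\);
  SE by the same bootstrap. Identical ratios short-circuit to the common
  value (the MAD-derived bandwidth would degenerate to zero).

`cochranQ()` reports \(Q = \sum w_j(\hat\theta_j - \hat\theta_{IVW})^2\)
with n - 1 degrees of freedom. All estimators are invariant to a joint
sign flip of \((\beta_X, \beta_Y)\) — allele coding cannot change the
causal estimate — and the weighted median with equal weights equals the
plain median.

# Cytokine prediction

`cvCompare()` runs a paired 10 x 2-fold cross-validation per cytokine:
covariates are regressed out of the cytokine first (consistent with the
correlation stages; whether the original procedure also pre-residualized
the metabolite block is unstated — here metabolites enter on the log10
scale un-residualized, and SNP and metabolite screens are covariate-
adjusted), then within each training fold predictors are selected (SNPs at
marginal p < 5e-5, metabolites at adjusted-Spearman p < 0.001) and two
elastic nets are fitted — SNPs only, and SNPs plus metabolites — with
mixing parameter 0.5 and penalty chosen by internal cross-validation on
the training fold. Accuracy is the Spearman correlation between held-out
measured and predicted values; the split indices are identical across the
two model tags, so the per-cytokine comparison is a paired two-sided
t-test over the 20 per-split correlations, BH-adjusted across cytokines.
Pairing is the only defensible reading given shared splits. An empty
predictor set degenerates to the intercept (rho recorded as 0) rather than
erroring, since a null cytokine is a legitimate outcome.

# The synthetic-data generator

The generator defines the study conditions under which everything above is
validated; its defaults are fixed once and are not tuned against test
outcomes.

* **Genotypes** (`simulateGenotypes()`): two latent standard-normal
  haplotype processes per block with AR(1) correlation `rho` between
  adjacent SNPs, thresholded at the MAF quantile; the allele sum is the
  dosage. This yields exact per-SNP Hardy-Weinberg proportions and
  tunable adjacent r-squared without coalescent machinery. Blocks sit on
  separate chromosomes with 5-kb SNP spacing.
* **Metabolome** (`simulateMetabolome()`): each feature is built on a
  latent log10 scale as standardized-dosage effects (effect sizes
  parameterized by variance fraction, so a planted fraction is directly
  the quantity the genetic-variance estimator should recover), covariate
  effects, and Gaussian noise scaled so the shares sum to one, then
  exponentiated base 10. Cohort covariates emulate a young-adult
  population: age truncated-normal around 28 (range 18-75), 55% female,
  contraceptive use in 40% of females.
* **Cytokines** (`simulateImmune()`): linear combinations of standardized
  log-metabolites and/or dosages plus Gaussian noise — the assay noise
  model is unstated in the source material, and Gaussian noise on the log
  scale is assumed.
* **GWAS pairs** (`simulateGwasPair()`): per-SNP effect estimates drawn
  analytically around their truth with \(se = 1/\sqrt{2p(1-p)n}\)
  (unit-variance trait), rather than simulating two full cohorts — faster
  and sufficient for colocalization/MR validation, with scenarios
  `shared_causal` (outcome effect = theta x exposure effect at the same
  SNPs), `distinct_causal` and `null`. SNPs are generated without LD so
  that "independent instruments" holds by construction.
* Each generator seeds its own derived RNG substream, so passing the same
  user seed to different generators cannot couple their noise.

What the generator does **not** emulate — population structure, imputation
uncertainty, batch/seasonal effects, LD between instruments, non-Gaussian
assay noise, missingness mechanisms — bounds what passing tests show:
recovery and calibration results demonstrate correctness of the
estimators under the stated model, not robustness to every artefact of
real cohort data.

**Preset scenarios.** `paperLikeFractions()` returns 49 genetic-variance
fractions on a geometric grid from 1.3% to 67.6% with the middle value
pinned at 8.1%, emulating the reported spread of per-metabolite genetic
variance. The MR recovery preset uses 8 independent instruments each
explaining 5% of the exposure (strong mQTL-grade instruments) at
n = 50,000 per trait and theta = -0.07; at this strength all four
estimators concentrate within ±0.02 of the truth. The demo's
colocalization pair uses a 10x larger outcome GWAS, the usual situation
for a metabolite exposure against a large disease GWAS, so the shared
variant is detectable in both traits even at a small causal effect.

# Problem sizes

The shipped tests and the acceptance script use deliberately modest sizes
chosen to make Monte-Carlo statements stable: null-calibration scans at
n = 500 with 10^4 pairs; CI-coverage at n = 2000 over 300-400 replicates;
genetic-variance recovery at n = 5000 with three replicate cohorts of 49
features; MR and colocalization at n = 50,000 per trait (summary
statistics are generated analytically, so large n is free); prediction
comparison at n = 300 with 10 x 2 folds.

# Known limitations

* One causal variant per trait per region (no SuSiE-style multi-causal
  colocalization; no conditional analysis).
* MR is limited to the four ratio-based estimators; no MR-Egger intercept
  or outlier-removal variants.
* The LD reference for instrument pruning must be supplied; without one,
  pruning is skipped with a logged note.
* The explained-variance procedure reuses data between selection and fit
  (by design, matching the emulated procedure); its reported values carry
  the corresponding optimism, bounded by the null simulations.
* Annotation is purely positional; no external effect predictors or
  pathway services are consulted.
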