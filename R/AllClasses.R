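#' @import methods
NULL

#' GenotypeMatrix: samples x SNPs dosage matrix with per-SNP metadata
#'
#' Dosages are alternate-allele counts in \[0, 2\] (missing allowed). The
#' `snps` slot carries per-SNP metadata: `id`, `chrom`, `pos` (1-based),
#' `ref`, `alt`, `maf` (minor-allele frequency on non-missing dosages).
#'
#' @slot dosage numeric matrix, samples in rows, SNPs in columns.
#' @slot snps data.frame of per-SNP metadata, one row per column of `dosage`.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(dosage = "matrix", snps = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  msgs <- character()
  d <- object@dosage
  s <- object@snps
  need <- c("id", "chrom", "pos", "ref", "alt", "maf")
  if (!all(need %in% names(s)))
    msgs <- c(msgs, paste("snps must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(s) != ncol(d)) msgs <- c(msgs, "nrow(snps) must equal ncol(dosage)")
    if (anyDuplicated(s$id)) msgs <- c(msgs, "SNP ids must be unique")
    if (any(s$pos <= 0)) msgs <- c(msgs, "pos must be strictly positive")
    if (any(s$maf < 0 | s$maf > 0.5, na.rm = TRUE))
      msgs <- c(msgs, "maf must lie in [0, 0.5]")
  }
  rng <- range(d, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    msgs <- c(msgs, "dosages must lie in [0, 2]")
  if (anyDuplicated(rownames(d))) msgs <- c(msgs, "sample ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' FeatureMatrix: samples x features measurement matrix with a platform tag
#'
#' @slot values numeric matrix, samples in rows, features in columns
#'   (missing allowed).
#' @slot platform one of "BM", "GM", "UM", "cytokine", "cellcount", "other".
#' @slot features data.frame with at least an `id` column, optionally an
#'   `annotation` column (metabolite name or m/z).
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(values = "matrix", platform = "character",
                 features = "data.frame"))

setValidity("FeatureMatrix", function(object) {
  msgs <- character()
  if (!object@platform %in% c("BM", "GM", "UM", "cytokine", "cellcount", "other"))
    msgs <- c(msgs, "platform must be one of BM, GM, UM, cytokine, cellcount, other")
  if (!"id" %in% names(object@features))
    msgs <- c(msgs, "features must have an id column")
  else if (nrow(object@features) != ncol(object@values))
    msgs <- c(msgs, "nrow(features) must equal ncol(values)")
  else if (anyDuplicated(object@features$id))
    msgs <- c(msgs, "feature ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' SummaryStats: per-SNP GWAS effect table for one trait
#'
#' Required columns of `stats`: `snp`, `ea` (effect allele), `oa` (other
#' allele), `eaf` in (0,1), `beta`, `se` > 0, `p` in (0,1\], `n`; `chrom`
#' and `pos` optional.
#'
#' @slot stats data.frame of per-SNP records.
#' @slot traitType "quantitative" or "case_control".
#' @slot caseFraction numeric; case fraction for case-control traits
#'   (length zero otherwise).
#' @exportClass SummaryStats
setClass("SummaryStats",
  representation(stats = "data.frame", traitType = "character",
                 caseFraction = "numeric"))

setValidity("SummaryStats", function(object) {
  msgs <- character()
  s <- object@stats
  need <- c("snp", "ea", "oa", "eaf", "beta", "se", "p", "n")
  miss <- setdiff(need, names(s))
  if (length(miss))
    msgs <- c(msgs, paste("missing columns:", paste(miss, collapse = ", ")))
  else {
    if (any(s$se <= 0)) msgs <- c(msgs, "se must be > 0")
    if (any(s$eaf <= 0 | s$eaf >= 1)) msgs <- c(msgs, "eaf must lie in (0, 1)")
    if (any(s$p <= 0 | s$p > 1)) msgs <- c(msgs, "p must lie in (0, 1]")
  }
  if (!object@traitType %in% c("quantitative", "case_control"))
    msgs <- c(msgs, "traitType must be quantitative or case_control")
  if (length(msgs)) msgs else TRUE
})

#' ColocResult: colocalization posteriors and per-SNP log-ABFs
#'
#' @slot pp named numeric of posterior probabilities for hypotheses H0-H4.
#' @slot labf1,labf2 per-SNP log approximate Bayes factors for each trait.
#' @slot priors named numeric (p1, p2, p12).
#' @slot m SNP count in the region.
#' @exportClass ColocResult
setClass("ColocResult",
  representation(pp = "numeric", labf1 = "numeric", labf2 = "numeric",
                 priors = "numeric", m = "integer"))

setValidity("ColocResult", function(object) {
  msgs <- character()
  if (length(object@pp) != 5) msgs <- c(msgs, "pp must have 5 entries (H0-H4)")
  if (abs(sum(object@pp) - 1) > 1e-9) msgs <- c(msgs, "pp must sum to 1")
  if (any(object@pp < 0)) msgs <- c(msgs, "pp must be non-negative")
  if (object@m < 1L) msgs <- c(msgs, "m must be >= 1")
  if (object@m == 1L && object@pp[["H3"]] != 0)
    msgs <- c(msgs, "single-SNP region must have PP(H3) = 0")
  if (length(msgs)) msgs else TRUE
})

#' MRResult: one Mendelian-randomization estimate
#'
#' @slot method one of "ivw", "weighted_median", "simple_mode", "weighted_mode".
#' @slot estimate,se,p causal estimate, its standard error and two-sided
#'   normal p-value.
#' @slot nInstruments number of instruments used.
#' @slot hetQ,hetDf,hetP Cochran's Q heterogeneity statistic, its degrees of
#'   freedom and chi-square p-value (populated for IVW, NA otherwise).
#' @exportClass MRResult
setClass("MRResult",
  representation(method = "character", estimate = "numeric", se = "numeric",
                 p = "numeric", nInstruments = "integer", hetQ = "numeric",
                 hetDf = "numeric", hetP = "numeric"))

setValidity("MRResult", function(object) {
  msgs <- character()
  if (!object@method %in% c("ivw", "weighted_median", "simple_mode", "weighted_mode"))
    msgs <- c(msgs, "unknown method")
  if (object@nInstruments < 1L) msgs <- c(msgs, "nInstruments must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' TruthLedger: planted parameters of a synthetic scenario
#'
#' @slot snpEffects data.frame (snp, feature, beta) of planted genetic
#'   effects in feature-SD units.
#' @slot covariateEffects data.frame (covariate, feature, beta).
#' @slot theta planted causal effect of the exposure on the outcome.
#' @slot scenario "null", "shared_causal" or "distinct_causal" (or "" when
#'   not a two-trait scenario).
#' @slot targetGeneticVariance per-feature planted genetic variance
#'   fractions, each in \[0, 1\].
#' @exportClass TruthLedger
setClass("TruthLedger",
  representation(snpEffects = "data.frame", covariateEffects = "data.frame",
                 theta = "numeric", scenario = "character",
                 targetGeneticVariance = "numeric"))

setValidity("TruthLedger", function(object) {
  msgs <- character()
  if (length(object@scenario) == 1 &&
      !object@scenario %in% c("", "null", "shared_causal", "distinct_causal"))
    msgs <- c(msgs, "unknown scenario")
  v <- object@targetGeneticVariance
  if (length(v) && any(v < 0 | v > 1))
    msgs <- c(msgs, "targetGeneticVariance must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' ResidualizedMatrix: covariate-adjusted feature residuals
#'
#' @slot values samples x features matrix of OLS residuals.
#' @slot covariatesUsed ordered covariate names.
#' @slot model list of per-feature coefficient vectors
#'   (intercept + covariates).
#' @exportClass ResidualizedMatrix
setClass("ResidualizedMatrix",
  representation(values = "matrix", covariatesUsed = "character",
                 model = "list"))
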