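#' Accessors for the core data classes
#'
#' `dosages()` returns the samples x SNPs dosage matrix, `snpInfo()` the
#' per-SNP metadata, `featureValues()` the samples x features matrix,
#' `platform()` the platform tag, `featureInfo()` the feature metadata,
#' `sampleIds()` the ordered sample identifiers, `sumStats()` the summary
#' statistics table, and `posteriors()` the colocalization posterior vector.
#'
#' @param x an object of the corresponding class.
#' @return the slot contents (a matrix, data.frame or vector; see above).
#' @name accessors
#' @aliases dosages snpInfo featureValues platform featureInfo sampleIds
#'   sumStats posteriors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("platform", function(x) standardGeneric("platform"))
#' @rdname accessors
#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("sumStats", function(x) standardGeneric("sumStats"))
#' @rdname accessors
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))

#' @rdname accessors
setMethod("dosages", "GenotypeMatrix", function(x) x@dosage)
#' @rdname accessors
setMethod("snpInfo", "GenotypeMatrix", function(x) x@snps)
#' @rdname accessors
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@dosage))
#' @rdname accessors
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
#' @rdname accessors
setMethod("platform", "FeatureMatrix", function(x) x@platform)
#' @rdname accessors
setMethod("featureInfo", "FeatureMatrix", function(x) x@features)
#' @rdname accessors
setMethod("sampleIds", "FeatureMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("featureValues", "ResidualizedMatrix", function(x) x@values)
#' @rdname accessors
setMethod("sampleIds", "ResidualizedMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("sumStats", "SummaryStats", function(x) x@stats)
#' @rdname accessors
setMethod("posteriors", "ColocResult", function(x) x@pp)

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosage), "samples x",
      ncol(object@dosage), "SNPs\n")
  cat("  chromosomes:", paste(unique(object@snps$chrom), collapse = ", "), "\n")
  cat("  MAF range: [", sprintf("%.3f", min(object@snps$maf)), ", ",
      sprintf("%.3f", max(object@snps$maf)), "]\n", sep = "")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix (", object@platform, "): ", nrow(object@values),
      " samples x ", ncol(object@values), " features\n", sep = "")
  nmiss <- sum(!is.finite(object@values))
  if (nmiss > 0) cat("  missing entries:", nmiss, "\n")
})

setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats (", object@traitType, "): ", nrow(object@stats),
      " SNPs\n", sep = "")
  cat("  min p:", format(min(object@stats$p), digits = 3), "\n")
})

setMethod("show", "ColocResult", function(object) {
  cat("ColocResult over", object@m, "SNPs\n")
  print(round(object@pp, 4))
})

setMethod("show", "MRResult", function(object) {
  cat(sprintf("MRResult [%s]: estimate = %.4f (se %.4f), p = %.3g, %d instruments\n",
              object@method, object@estimate, object@se, object@p,
              object@nInstruments))
  if (is.finite(object@hetQ))
    cat(sprintf("  Cochran's Q = %.3f (df %d), p = %.3g\n", object@hetQ,
                as.integer(object@hetDf), object@hetP))
})

setMethod("show", "TruthLedger", function(object) {
  cat("TruthLedger:", nrow(object@snpEffects), "planted SNP effects,",
      nrow(object@covariateEffects), "covariate effects\n")
  if (nzchar(object@scenario))
    cat("  scenario:", object@scenario, " theta:", object@theta, "\n")
})

#' Construct a FeatureMatrix
#'
#' @param values samples x features numeric matrix with sample row names and
#'   feature column names.
#' @param platform platform tag ("BM", "GM", "UM", "cytokine", "cellcount",
#'   "other").
#' @param annotation optional character vector of feature annotations.
#' @return a [FeatureMatrix-class] object.
#' @export
FeatureMatrix <- function(values, platform = "other", annotation = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("feat_", seq_len(ncol(values)))
  feats <- data.frame(id = colnames(values), stringsAsFactors = FALSE)
  if (!is.null(annotation)) feats$annotation <- annotation
  new("FeatureMatrix", values = values, platform = platform, features = feats)
}

#' Construct a GenotypeMatrix
#'
#' @param dosage samples x SNPs numeric matrix of alternate-allele dosages.
#' @param snps data.frame with columns id, chrom, pos, ref, alt (maf is
#'   recomputed from the dosages if absent).
#' @return a [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(dosage, snps) {
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- snps$id
  if (!"maf" %in% names(snps)) {
    af <- colMeans(dosage, na.rm = TRUE) / 2
    snps$maf <- pmin(af, 1 - af)
  }
  new("GenotypeMatrix", dosage = dosage, snps = as.data.frame(snps))
}

#' Construct a SummaryStats object
#'
#' Allele columns are normalized to upper case. A warning is raised when a
#' stored p-value disagrees with the two-sided normal p implied by beta/se
#' by more than 10% relative tolerance.
#'
#' @param stats data.frame with columns snp, ea, oa, eaf, beta, se, p, n
#'   (chrom and pos optional).
#' @param traitType "quantitative" or "case_control".
#' @param caseFraction case fraction for case-control traits.
#' @return a [SummaryStats-class] object.
#' @export
SummaryStats <- function(stats, traitType = "quantitative",
                         caseFraction = numeric()) {
  stats <- as.data.frame(stats)
  stats$ea <- toupper(stats$ea)
  stats$oa <- toupper(stats$oa)
  z <- abs(stats$beta / stats$se)
  pImplied <- 2 * pnorm(-z)
  bad <- pImplied > 1e-300 & abs(stats$p - pImplied) / pImplied > 0.1
  if (any(bad, na.rm = TRUE))
    warning(sum(bad, na.rm = TRUE),
            " rows have p inconsistent with |beta/se| beyond 10% relative tolerance")
  new("SummaryStats", stats = stats, traitType = traitType,
      caseFraction = caseFraction)
}
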