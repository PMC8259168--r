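#' Log-transform a feature matrix
#'
#' Element-wise log (base 10 by default). Under the `half_min` policy zeros
#' are replaced by half the smallest positive value of the same feature;
#' under `error` any zero aborts. Negative values always abort, naming the
#' offending feature.
#'
#' @param m a [FeatureMatrix-class] with non-negative values.
#' @param base logarithm base (default 10).
#' @param zeroPolicy "half_min" or "error".
#' @return a [FeatureMatrix-class] of transformed values.
#' @export
logTransform <- function(m, base = 10, zeroPolicy = c("half_min", "error")) {
  zeroPolicy <- match.arg(zeroPolicy)
  vals <- featureValues(m)
  neg <- which(colSums(vals < 0, na.rm = TRUE) > 0)
  if (length(neg))
    stop("negative values in feature(s): ",
         paste(featureInfo(m)$id[neg], collapse = ", "))
  zero <- which(colSums(vals == 0, na.rm = TRUE) > 0)
  if (length(zero)) {
    if (zeroPolicy == "error")
      stop("zero values in feature(s): ",
           paste(featureInfo(m)$id[zero], collapse = ", "))
    for (j in zero) {
      pos <- vals[, j][vals[, j] > 0 & is.finite(vals[, j])]
      if (!length(pos)) stop("feature ", featureInfo(m)$id[j],
                             " is all-zero; half_min undefined")
      vals[, j][vals[, j] == 0] <- min(pos) / 2
    }
  }
  out <- log(vals, base = base)
  new("FeatureMatrix", values = out, platform = platform(m),
      features = featureInfo(m))
}

#' PCA-based sample outlier detection
#'
#' Features are z-scored (missing entries mean-imputed, logged) and samples
#' whose PC1 or PC2 score lies more than `sdThreshold` standard deviations
#' from that component's mean are flagged. Input is expected on the log10
#' scale.
#'
#' @param m a [FeatureMatrix-class] (log-transformed).
#' @param sdThreshold flagging threshold in SD units (default 4).
#' @return list with `kept` and `flagged` sample id vectors and `scores`
#'   (samples x 2 matrix of PC1/PC2 scores).
#' @export
pcaOutliers <- function(m, sdThreshold = 4) {
  vals <- featureValues(m)
  if (nrow(vals) < 3) stop("need at least 3 samples for PCA")
  nmiss <- sum(!is.finite(vals))
  if (nmiss > 0) mqNote("pcaOutliers: mean-imputed %d missing entries", nmiss)
  z <- zScore(meanImpute(vals))
  pc <- prcomp(z, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  if (k < 2) scores <- cbind(scores, 0)
  colnames(scores) <- c("PC1", "PC2")
  flag <- rep(FALSE, nrow(scores))
  for (j in 1:2) {
    sdj <- sd(scores[, j])
    if (is.finite(sdj) && sdj > 0)
      flag <- flag | abs(scores[, j] - mean(scores[, j])) > sdThreshold * sdj
  }
  ids <- sampleIds(m)
  list(kept = ids[!flag], flagged = ids[flag], scores = scores)
}

#' Per-feature Shapiro-Wilk normality report
#'
#' Report only; no filtering is performed. Constant features (or features
#' with fewer than 3 non-missing values) are reported with undefined W/p.
#' Shapiro-Wilk is limited to 5000 observations; larger features use the
#' first 5000 non-missing values.
#'
#' @param m a [FeatureMatrix-class].
#' @return data.frame (feature, n, W, p, note).
#' @export
normalityReport <- function(m) {
  vals <- featureValues(m)
  ids <- featureInfo(m)$id
  out <- lapply(seq_len(ncol(vals)), function(j) {
    x <- vals[, j][is.finite(vals[, j])]
    if (length(x) < 3)
      return(data.frame(feature = ids[j], n = length(x), W = NA_real_,
                        p = NA_real_, note = "fewer than 3 values"))
    if (sd(x) == 0)
      return(data.frame(feature = ids[j], n = length(x), W = NA_real_,
                        p = NA_real_, note = "constant"))
    if (length(x) > 5000) x <- x[seq_len(5000)]
    sw <- shapiro.test(x)
    data.frame(feature = ids[j], n = length(x), W = unname(sw$statistic),
               p = sw$p.value, note = "")
  })
  do.call(rbind, out)
}

#' Regress covariates out of every feature
#'
#' Per-feature ordinary least squares on the covariates (with intercept),
#' complete-case per feature; residuals are returned with missing entries
#' preserved. Rank-deficient covariate matrices abort, listing the
#' collinear columns.
#'
#' @param m a [FeatureMatrix-class] or numeric matrix.
#' @param covariates data.frame of covariates aligned with the samples.
#' @return a [ResidualizedMatrix-class].
#' @export
residualize <- function(m, covariates) {
  vals <- if (is(m, "FeatureMatrix")) featureValues(m) else as.matrix(m)
  X <- covariateDesign(covariates, nrow(vals))
  out <- vals
  models <- vector("list", ncol(vals))
  names(models) <- colnames(vals)
  for (j in seq_len(ncol(vals))) {
    ok <- is.finite(vals[, j])
    fit <- lm.fit(X[ok, , drop = FALSE], vals[ok, j])
    out[ok, j] <- fit$residuals
    out[!ok, j] <- NA_real_
    models[[j]] <- fit$coefficients
  }
  new("ResidualizedMatrix", values = out,
      covariatesUsed = setdiff(colnames(X), "(Intercept)"), model = models)
}
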