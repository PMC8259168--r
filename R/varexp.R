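#' Adjusted R-squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)`, the explained-variance metric
#' used throughout: R-squared penalized for the number of predictors.
#'
#' @param r2 R-squared in \[0, 1\].
#' @param n number of observations.
#' @param p number of predictors (excluding the intercept).
#' @return adjusted R-squared (may be negative).
#' @examples
#' adjustedR2(0.5, 100, 10)  # 0.44382...
#' @export
adjustedR2 <- function(r2, n, p) {
  if (n <= p + 1) stop("saturated model: need n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Multi-step explained-variance estimation
#'
#' Implements the association-screened multivariate procedure:
#' (1) candidates associated with the response at adjusted-Spearman
#' p < `pThreshold` are selected; (2) response and selected candidates are
#' residualized on the covariates; (3) collinear candidates (pairwise
#' Pearson |r| > `collinearityR`) are greedily dropped, keeping the member
#' with the smaller marginal p; (4) the residual response is regressed on
#' the survivors and the total model adjusted R-squared is reported.
#' Negative adjusted R-squared is clamped to 0 for reporting (explained
#' variance cannot be negative); the raw value is retained.
#'
#' @param response numeric response vector (one phenotype).
#' @param candidates a [FeatureMatrix-class] or numeric matrix of candidate
#'   explanatory features.
#' @param covariates optional covariate data.frame.
#' @param pThreshold marginal selection threshold (0.001 for metabolite
#'   candidates, 0.05 for other feature classes).
#' @param collinearityR pairwise correlation threshold (default 0.9).
#' @return list (VarExpResult): `keptFeatures`, `droppedCollinear`, `r2`,
#'   `adjR2`, `clampedAdjR2`, `n`, `pFeatures`.
#' @export
explainVariance <- function(response, candidates, covariates = NULL,
                            pThreshold = 0.05, collinearityR = 0.9) {
  C <- if (is(candidates, "FeatureMatrix")) featureValues(candidates)
       else as.matrix(candidates)
  n <- length(response)
  stopifnot(nrow(C) == n)
  if (n < 30) stop("need at least 30 observations")
  ## (1) marginal screening
  scan <- adjustedSpearmanScan(C, matrix(response, ncol = 1,
                                         dimnames = list(NULL, "response")),
                               covariates = covariates)
  sel <- scan$feature_a[!is.na(scan$p) & scan$p < pThreshold]
  marginalP <- setNames(scan$p, scan$feature_a)
  empty <- list(keptFeatures = character(), droppedCollinear = character(),
                r2 = 0, adjR2 = 0, clampedAdjR2 = 0, n = n, pFeatures = 0L)
  if (!length(sel)) return(empty)
  ## (2) residualize on covariates
  X <- covariateDesign(covariates, n)
  yRes <- residualizeColumns(matrix(response, ncol = 1), X)[, 1]
  CRes <- residualizeColumns(C[, sel, drop = FALSE], X)
  ## (3) greedy collinearity removal, best marginal p first
  ord <- sel[order(marginalP[sel])]
  kept <- character()
  dropped <- character()
  for (f in ord) {
    if (length(kept)) {
      r <- suppressWarnings(cor(CRes[, f], CRes[, kept, drop = FALSE],
                                use = "pairwise"))
      if (any(abs(r) > collinearityR, na.rm = TRUE)) {
        dropped <- c(dropped, f)
        next
      }
    }
    kept <- c(kept, f)
  }
  if (length(kept) >= n - 2)
    stop("over-parameterized: ", length(kept), " features for n = ", n)
  ## (4) multivariate OLS on survivors
  fit <- lm(yRes ~ ., data = as.data.frame(CRes[, kept, drop = FALSE]))
  r2 <- summary(fit)$r.squared
  adj <- adjustedR2(r2, n, length(kept))
  list(keptFeatures = kept, droppedCollinear = dropped, r2 = r2,
       adjR2 = adj, clampedAdjR2 = max(adj, 0), n = n,
       pFeatures = length(kept))
}
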