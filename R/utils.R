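#' @importFrom stats cor pt pnorm qnorm rnorm runif rbinom sd lm lm.fit
#' @importFrom stats p.adjust prcomp shapiro.test fisher.test dist hclust
#' @importFrom stats complete.cases density mad median quantile setNames
#' @importFrom stats pchisq predict t.test coef residuals var aggregate
#' @importFrom utils read.delim write.table head packageVersion
NULL

## structured logging to stderr; kept deliberately plain so pipelines can grep it
mqNote <- function(fmt, ...) message(sprintf(paste0("[metaboQTL] ", fmt), ...))

#' Numerically stable log(sum(exp(x)))
#' @param x numeric vector of log-scale values.
#' @return scalar log-sum-exp.
#' @keywords internal
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Spearman correlation with average ranks and the t approximation for p
## (used for n > 10 throughout; pairs with fewer complete observations are
## reported with an undefined p).
spearmanPair <- function(x, y, minN = 10L) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < minN) {
    return(list(n = n, rho = NA_real_, p = NA_real_))
  }
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(n = n, rho = NA_real_, p = NA_real_))
  }
  rho <- cor(rx, ry)
  p <- spearmanPValue(rho, n)
  list(n = n, rho = rho, p = p)
}

spearmanPValue <- function(rho, n) {
  rho <- pmin(1, pmax(-1, rho))
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pmax(2 * pt(-abs(tval), df = n - 2), .Machine$double.xmin)
}

## column-wise z-score; zero-variance columns become all-zero instead of NaN
zScore <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}

## mean-impute missing entries per column (analysis-time only, never persisted)
meanImpute <- function(x) {
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) {
    nas <- !is.finite(x[, j])
    if (any(nas)) x[nas, j] <- mean(x[!nas, j])
  }
  x
}

## covariate design matrix with intercept; errors on rank deficiency naming
## the collinear columns
covariateDesign <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)")))
  }
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  X <- cbind("(Intercept)" = 1, as.matrix(covariates))
  storage.mode(X) <- "double"
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("covariate matrix is rank-deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  X
}

## residualize the columns of y on covariate design X (complete cases per
## column, NA preserved in the output)
residualizeColumns <- function(y, X) {
  y <- as.matrix(y)
  out <- y
  full <- complete.cases(y)
  if (all(full)) {
    fit <- lm.fit(X, y)
    out[] <- fit$residuals
    return(out)
  }
  for (j in seq_len(ncol(y))) {
    ok <- is.finite(y[, j])
    fit <- lm.fit(X[ok, , drop = FALSE], y[ok, j])
    out[ok, j] <- fit$residuals
    out[!ok, j] <- NA_real_
  }
  out
}

## deterministic child seeds derived from one user seed (kept < 2^31)
childSeed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7919L
}
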