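#' Covariate-adjusted Spearman association scan
#'
#' Every feature of `a` and `b` is first residualized on the covariates
#' (ordinary least squares with intercept), then Spearman's rho and its
#' t-approximation p-value are computed on the residual ranks for every
#' (a, b) pair. Benjamini-Hochberg adjustment is applied across the full
#' a x b grid of one call (one FDR family per scan). Pairs with fewer than
#' `minN` complete observations or a zero-variance residual are reported
#' with undefined rho/p.
#'
#' @param a,b [FeatureMatrix-class] objects (or numeric matrices) over the
#'   same samples.
#' @param covariates optional covariate data.frame; NULL means plain
#'   Spearman.
#' @param minN minimum paired complete observations (default 10).
#' @return data.frame (feature_a, feature_b, n_pairs, rho, p, q); the
#'   association table.
#' @export
adjustedSpearmanScan <- function(a, b, covariates = NULL, minN = 10L) {
  A <- if (is(a, "FeatureMatrix")) featureValues(a) else as.matrix(a)
  B <- if (is(b, "FeatureMatrix")) featureValues(b) else as.matrix(b)
  stopifnot(nrow(A) == nrow(B))
  if (!is.null(covariates)) {
    ## constant covariates carry no adjustment beyond the intercept
    covariates <- as.data.frame(covariates)
    keep <- vapply(covariates, function(x) sd(x, na.rm = TRUE) > 0, logical(1))
    if (any(!keep))
      mqNote("adjustedSpearmanScan: dropped %d constant covariate(s)",
             sum(!keep))
    covariates <- covariates[, keep, drop = FALSE]
    if (!ncol(covariates)) covariates <- NULL
  }
  if (!is.null(covariates)) {
    X <- covariateDesign(covariates, nrow(A))
    A <- residualizeColumns(A, X)
    B <- residualizeColumns(B, X)
  }
  if (!anyNA(A) && !anyNA(B)) {
    n <- nrow(A)
    rA <- apply(A, 2, rank)
    rB <- apply(B, 2, rank)
    sdA <- apply(rA, 2, sd)
    sdB <- apply(rB, 2, sd)
    rho <- suppressWarnings(cor(rA, rB))
    rho[sdA == 0, ] <- NA_real_
    rho[, sdB == 0] <- NA_real_
    grid <- expand.grid(ai = seq_len(ncol(A)), bi = seq_len(ncol(B)))
    rhoV <- rho[cbind(grid$ai, grid$bi)]
    pV <- ifelse(is.na(rhoV) | n < minN, NA_real_, spearmanPValue(rhoV, n))
    out <- data.frame(feature_a = colnames(A)[grid$ai],
                      feature_b = colnames(B)[grid$bi],
                      n_pairs = n, rho = rhoV, p = pV,
                      stringsAsFactors = FALSE)
  } else {
    grid <- expand.grid(ai = seq_len(ncol(A)), bi = seq_len(ncol(B)))
    res <- mapply(function(i, j) {
      s <- spearmanPair(A[, i], B[, j], minN = minN)
      c(s$n, s$rho, s$p)
    }, grid$ai, grid$bi)
    out <- data.frame(feature_a = colnames(A)[grid$ai],
                      feature_b = colnames(B)[grid$bi],
                      n_pairs = res[1, ], rho = res[2, ], p = res[3, ],
                      stringsAsFactors = FALSE)
  }
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Host-factor association scan with per-factor summaries
#'
#' Each factor (e.g. sex, age, BMI, contraceptive use; binary factors coded
#' 0/1) is tested against every feature by the same rank procedure as
#' [adjustedSpearmanScan()], after optionally pre-adjusting the features on
#' a covariate subset. BH adjustment is applied within each factor's
#' family. The summary reports, per factor, the fraction of features with
#' q < `fdr` and, among those, the fraction with positive rho.
#'
#' @param features a [FeatureMatrix-class].
#' @param factors data.frame of host factors (numeric coding).
#' @param preAdjust optional data.frame of covariates regressed out of the
#'   features (not the factors) first.
#' @param fdr significance level on q (default 0.05).
#' @return list with `assoc` (association table rows for all factors) and
#'   `summary` (per-factor fractionSignificant / fractionPositive).
#' @export
hostFactorScan <- function(features, factors, preAdjust = NULL, fdr = 0.05) {
  factors <- as.data.frame(factors)
  tabs <- lapply(names(factors), function(f) {
    tab <- adjustedSpearmanScan(features,
                                matrix(factors[[f]], ncol = 1,
                                       dimnames = list(NULL, f)),
                                covariates = preAdjust)
    tab$q <- p.adjust(tab$p, method = "BH")  # family = one factor
    tab
  })
  assoc <- do.call(rbind, tabs)
  summary <- do.call(rbind, lapply(tabs, function(tab) {
    sig <- !is.na(tab$q) & tab$q < fdr
    data.frame(factor = tab$feature_b[1],
               fractionSignificant = mean(sig),
               fractionPositive = if (any(sig)) mean(tab$rho[sig] > 0)
                                  else NA_real_)
  }))
  list(assoc = assoc, summary = summary)
}

#' Hierarchical clustering of a correlation matrix
#'
#' Complete-linkage agglomerative clustering on Euclidean distances between
#' the rho-vectors of rows (and of columns), as used for correlation
#' heatmaps. Undefined rho entries are imputed as 0 (logged). Leaf order is
#' the deterministic order produced by the merge tree.
#'
#' @param assoc an association table from [adjustedSpearmanScan()] or a
#'   numeric rho matrix.
#' @return list with `rowOrder`, `colOrder` (leaf-ordered labels) and the
#'   two `hclust` objects.
#' @export
clusterCorrelationMatrix <- function(assoc) {
  if (is.data.frame(assoc)) {
    rows <- unique(assoc$feature_a)
    cols <- unique(assoc$feature_b)
    rho <- matrix(NA_real_, length(rows), length(cols),
                  dimnames = list(rows, cols))
    rho[cbind(match(assoc$feature_a, rows), match(assoc$feature_b, cols))] <-
      assoc$rho
  } else {
    rho <- as.matrix(assoc)
  }
  nmiss <- sum(is.na(rho))
  if (nmiss > 0) {
    mqNote("clusterCorrelationMatrix: imputed %d undefined rho as 0", nmiss)
    rho[is.na(rho)] <- 0
  }
  orderOf <- function(mat) {
    if (nrow(mat) < 2)
      return(list(order = rownames(mat), hclust = NULL))
    hc <- hclust(dist(mat, method = "euclidean"), method = "complete")
    list(order = rownames(mat)[hc$order], hclust = hc)
  }
  ro <- orderOf(rho)
  co <- orderOf(t(rho))
  list(rowOrder = ro$order, colOrder = co$order,
       rowHclust = ro$hclust, colHclust = co$hclust)
}
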