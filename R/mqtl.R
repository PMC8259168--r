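#' Metabolite-QTL scan (additive linear model per SNP-feature pair)
#'
#' Features and dosages are residualized on the covariates once, then each
#' SNP-feature pair is tested by simple regression of the residuals; by the
#' Frisch-Waugh theorem the slope equals the full-model SNP coefficient,
#' and t and p are corrected to the full-model degrees of freedom
#' n - k - 2 (k = number of covariates). Missing dosages are mean-imputed
#' at analysis time; SNPs constant after imputation are skipped (logged).
#' Features are expected on the log10 scale; samples must already be
#' intersected across data sets.
#'
#' @param g a [GenotypeMatrix-class].
#' @param m a [FeatureMatrix-class] (log-transformed).
#' @param covariates optional covariate data.frame (age, sex, contraceptive
#'   use, cell abundances, ...).
#' @return data.frame of QTL records (snp, feature, beta, se, t, p, n, df);
#'   beta is in feature units per alt-allele dose.
#' @export
qtlScan <- function(g, m, covariates = NULL) {
  G <- meanImpute(dosages(g))
  Y <- if (is(m, "FeatureMatrix")) featureValues(m) else as.matrix(m)
  stopifnot(nrow(G) == nrow(Y))
  n <- nrow(G)
  k <- if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  X <- covariateDesign(covariates, n)
  Gres <- residualizeColumns(G, X)
  Yres <- residualizeColumns(Y, X)
  sdG <- apply(Gres, 2, sd)
  keepG <- sdG > 0
  if (any(!keepG))
    mqNote("qtlScan: skipped %d constant SNP(s)", sum(!keepG))
  Gres <- Gres[, keepG, drop = FALSE]
  sdG <- sdG[keepG]
  sdY <- apply(Yres, 2, sd)
  df <- n - k - 2L
  r <- suppressWarnings(cor(Gres, Yres))
  grid <- expand.grid(gi = seq_len(ncol(Gres)), fi = seq_len(ncol(Yres)))
  rv <- r[cbind(grid$gi, grid$fi)]
  rv <- pmin(1 - 1e-15, pmax(-1 + 1e-15, rv))
  tv <- rv * sqrt(df / (1 - rv^2))
  beta <- rv * sdY[grid$fi] / sdG[grid$gi]
  se <- abs(beta) / pmax(abs(tv), .Machine$double.eps)
  se[tv == 0] <- sdY[grid$fi][tv == 0] / (sdG[grid$gi][tv == 0] * sqrt(df))
  p <- 2 * pt(-abs(tv), df)
  data.frame(snp = colnames(Gres)[grid$gi],
             feature = colnames(Yres)[grid$fi],
             beta = beta, se = se, t = tv,
             p = pmax(p, .Machine$double.xmin), n = n, df = df,
             stringsAsFactors = FALSE)
}

#' Per-platform Bonferroni significance threshold
#'
#' Divides a genome-wide significance level by the number of features
#' tested on a platform, the correction used to declare metabolite QTLs
#' (e.g. 5e-8 / 231 = 2.16e-10 for a 231-feature platform).
#'
#' @param alphaGw genome-wide significance level (default 5e-8).
#' @param mFeatures number of features (>= 1).
#' @return the per-test threshold `alphaGw / mFeatures`.
#' @export
bonferroniThreshold <- function(alphaGw = 5e-8, mFeatures) {
  if (mFeatures < 1) stop("mFeatures must be >= 1")
  alphaGw / mFeatures
}

#' Greedy LD-based locus clumping
#'
#' Repeatedly takes the unassigned SNP with the smallest p as locus lead
#' and absorbs unassigned SNPs on the same chromosome within `windowBp`
#' whose squared dosage correlation with the lead exceeds `r2Threshold`.
#' Input records should already be filtered to a significance threshold.
#'
#' @param records QTL record data.frame (needs snp, feature, p).
#' @param g a [GenotypeMatrix-class] covering all record SNPs.
#' @param r2Threshold LD threshold (default 0.1).
#' @param windowBp maximum distance from the lead (default 1e6).
#' @return list of loci; each locus is a list with `lead`, `members`,
#'   `features`, `chrom`, `span` and `leadP`.
#' @export
clumpLoci <- function(records, g, r2Threshold = 0.1, windowBp = 1e6) {
  miss <- setdiff(unique(records$snp), snpInfo(g)$id)
  if (length(miss))
    stop("record SNP(s) absent from genotype matrix: ",
         paste(head(miss, 5), collapse = ", "))
  perSnp <- aggregate(p ~ snp, data = records, FUN = min)
  info <- snpInfo(g)
  perSnp$chrom <- info$chrom[match(perSnp$snp, info$id)]
  perSnp$pos <- info$pos[match(perSnp$snp, info$id)]
  D <- meanImpute(dosages(g)[, perSnp$snp, drop = FALSE])
  unassigned <- rep(TRUE, nrow(perSnp))
  loci <- list()
  while (any(unassigned)) {
    leadIdx <- which(unassigned)[which.min(perSnp$p[unassigned])]
    cand <- which(unassigned & perSnp$chrom == perSnp$chrom[leadIdx] &
                  abs(perSnp$pos - perSnp$pos[leadIdx]) <= windowBp)
    r2 <- suppressWarnings(
      as.vector(cor(D[, leadIdx], D[, cand, drop = FALSE]))^2)
    r2[is.na(r2)] <- 0
    take <- cand[r2 > r2Threshold | cand == leadIdx]
    unassigned[take] <- FALSE
    memberSnps <- perSnp$snp[take]
    loci[[length(loci) + 1L]] <- list(
      lead = perSnp$snp[leadIdx],
      members = memberSnps,
      features = unique(records$feature[records$snp %in% memberSnps]),
      chrom = perSnp$chrom[leadIdx],
      span = range(perSnp$pos[take]),
      leadP = perSnp$p[leadIdx])
  }
  loci
}

#' Genetic variance of a feature explained by lead SNPs
#'
#' Residualizes the feature on the covariates, regresses the residual on
#' the (post-clumping, independent) lead-SNP dosages and reports the total
#' model adjusted R-squared, clamped to 0 for reporting.
#'
#' @param feature numeric feature vector (log scale).
#' @param leads character vector of lead SNP ids (possibly empty).
#' @param g a [GenotypeMatrix-class].
#' @param covariates optional covariate data.frame.
#' @return list with `adjR2` (clamped), `rawAdjR2`, `r2`, `n`, `nLeads`.
#' @export
geneticVariance <- function(feature, leads, g, covariates = NULL) {
  n <- length(feature)
  if (!length(leads))
    return(list(adjR2 = 0, rawAdjR2 = 0, r2 = 0, n = n, nLeads = 0L))
  if (length(leads) >= n - 2)
    stop("too many lead SNPs (", length(leads), ") for n = ", n)
  miss <- setdiff(leads, snpInfo(g)$id)
  if (length(miss)) stop("unknown lead SNP(s): ", paste(miss, collapse = ", "))
  X <- covariateDesign(covariates, n)
  yRes <- residualizeColumns(matrix(feature, ncol = 1), X)[, 1]
  D <- meanImpute(dosages(g)[, leads, drop = FALSE])
  fit <- lm(yRes ~ D)
  r2 <- summary(fit)$r.squared
  adj <- adjustedR2(r2, n, length(leads))
  list(adjR2 = max(adj, 0), rawAdjR2 = adj, r2 = r2, n = n,
       nLeads = length(leads))
}
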