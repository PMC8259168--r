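#' Wakefield log approximate Bayes factor
#'
#' For a SNP with effect estimate `beta` and standard error `se`, under a
#' Gaussian effect prior with standard deviation `priorSdW`, the log
#' approximate Bayes factor is
#' `0.5 * (log(V / (V + W)) + z^2 * W / (V + W))` with `V = se^2`,
#' `z = beta / se`, `W = priorSdW^2`. Vectorized over SNPs.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), > 0.
#' @param priorSdW prior effect SD (0.15 for quantitative traits, 0.2 on
#'   the log-odds scale for case-control traits are the conventional
#'   defaults).
#' @return numeric vector of log ABFs.
#' @export
wakefieldLabf <- function(beta, se, priorSdW = 0.15) {
  if (any(se <= 0)) stop("se must be > 0")
  if (priorSdW <= 0) stop("priorSdW must be > 0")
  V <- se^2
  W <- priorSdW^2
  z2 <- (beta / se)^2
  0.5 * (log(V / (V + W)) + z2 * W / (V + W))
}

#' Colocalization posterior probabilities from per-SNP log-ABFs
#'
#' Assuming at most one causal variant per trait, the unnormalized
#' hypothesis weights over a region of m SNPs are
#' (1, p1*L1, p2*L2, p1*p2*(L1*L2 - L12), p12*L12) with
#' L1 = sum(exp(labf1)), L2 = sum(exp(labf2)),
#' L12 = sum(exp(labf1 + labf2)); all sums are evaluated in log space
#' (log-sum-exp) to avoid overflow. The H3 mass L1*L2 - L12 (the sum over
#' ordered pairs of distinct SNPs) is clamped at 0 if floating-point error
#' drives it negative (logged).
#'
#' @param labf1,labf2 equal-length per-SNP log-ABF vectors over the same
#'   SNPs.
#' @param p1,p2 prior probabilities that a SNP is causal for trait 1 / 2
#'   (default 1e-4).
#' @param p12 prior probability that a SNP is causal for both (default
#'   1e-5).
#' @return a [ColocResult-class] with posteriors PP(H0)..PP(H4).
#' @export
colocPosteriors <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  if (length(labf1) != length(labf2))
    stop("labf1 and labf2 must have equal length")
  m <- length(labf1)
  if (m < 1) stop("need at least one SNP")
  l1 <- logSumExp(labf1)
  l2 <- logSumExp(labf2)
  l12 <- logSumExp(labf1 + labf2)
  ## log(L1*L2 - L12) via log1p; the pair sum cannot exceed the product sum
  diff <- l12 - (l1 + l2)
  if (diff >= 0) {
    if (diff > 1e-9 && m > 1)
      mqNote("colocPosteriors: H3 mass clamped at 0 (float cancellation)")
    logH3mass <- -Inf
  } else {
    logH3mass <- l1 + l2 + log1p(-exp(diff))
  }
  logW <- c(H0 = 0,
            H1 = log(p1) + l1,
            H2 = log(p2) + l2,
            H3 = log(p1) + log(p2) + logH3mass,
            H4 = log(p12) + l12)
  pp <- exp(logW - logSumExp(logW))
  pp <- pp / sum(pp)
  if (m == 1) pp[["H3"]] <- 0
  new("ColocResult", pp = pp, labf1 = labf1, labf2 = labf2,
      priors = c(p1 = p1, p2 = p2, p12 = p12), m = as.integer(m))
}

#' Colocalization of two traits' summary statistics over a region
#'
#' Convenience wrapper: intersects the two tables on SNP id, computes
#' Wakefield log-ABFs per trait (prior SD 0.15 for quantitative traits,
#' 0.2 for case-control) and calls [colocPosteriors()].
#'
#' @param stats1,stats2 [SummaryStats-class] objects sharing SNP ids.
#' @param p1,p2,p12 hypothesis priors (see [colocPosteriors()]).
#' @param priorSd1,priorSd2 optional prior effect SDs overriding the
#'   trait-type defaults.
#' @return a [ColocResult-class].
#' @export
colocRegion <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                        priorSd1 = NULL, priorSd2 = NULL) {
  s1 <- sumStats(stats1)
  s2 <- sumStats(stats2)
  common <- intersect(s1$snp, s2$snp)
  if (!length(common)) stop("no shared SNPs between the two traits")
  s1 <- s1[match(common, s1$snp), ]
  s2 <- s2[match(common, s2$snp), ]
  defaultSd <- function(s, override) {
    if (!is.null(override)) return(override)
    if (s@traitType == "case_control") 0.2 else 0.15
  }
  labf1 <- wakefieldLabf(s1$beta, s1$se, defaultSd(stats1, priorSd1))
  labf2 <- wakefieldLabf(s2$beta, s2$se, defaultSd(stats2, priorSd2))
  names(labf1) <- names(labf2) <- common
  colocPosteriors(labf1, labf2, p1 = p1, p2 = p2, p12 = p12)
}
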