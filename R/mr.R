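#' Instrument selection and allele harmonization for two-sample MR
#'
#' Steps, with per-step attrition logged: (1) keep SNPs with exposure
#' p < `pThreshold`; (2) greedy LD pruning by ascending exposure p at
#' squared dosage correlation < `r2Threshold` against the reference panel
#' (skipped with a note when `ldRef` is NULL); (3) align the outcome
#' effect allele to the exposure effect allele, flipping the outcome beta
#' sign and eaf when the alleles are swapped, dropping SNPs whose alleles
#' cannot be reconciled; (4) drop palindromic (A/T, C/G) SNPs with
#' exposure eaf inside `palindromicWindow`, where strand cannot be
#' resolved from frequency.
#'
#' @param exposure,outcome [SummaryStats-class] objects sharing SNP ids.
#' @param pThreshold exposure significance threshold (default 5e-8).
#' @param r2Threshold LD pruning threshold (default 0.01).
#' @param ldRef optional [GenotypeMatrix-class] LD reference covering the
#'   candidate SNPs.
#' @param palindromicWindow eaf window for dropping palindromic SNPs
#'   (default c(0.42, 0.58)).
#' @return instrument table: data.frame (snp, betaX, seX, betaY, seY,
#'   ratio, ratioSe, weight) with the Wald ratio `betaY/betaX`, its
#'   first-order SE `seY/|betaX|` and inverse-variance weight.
#' @export
harmonizeAndSelect <- function(exposure, outcome, pThreshold = 5e-8,
                               r2Threshold = 0.01, ldRef = NULL,
                               palindromicWindow = c(0.42, 0.58)) {
  ex <- sumStats(exposure)
  out <- sumStats(outcome)
  counts <- c(candidates = nrow(ex))
  ex <- ex[ex$p < pThreshold & ex$snp %in% out$snp, , drop = FALSE]
  counts["significant"] <- nrow(ex)
  ## greedy LD prune, best exposure p first
  if (nrow(ex) > 1 && !is.null(ldRef)) {
    have <- ex$snp %in% snpInfo(ldRef)$id
    if (!all(have)) stop("ld_ref does not cover candidate SNP(s): ",
                         paste(head(ex$snp[!have], 5), collapse = ", "))
    D <- meanImpute(dosages(ldRef)[, ex$snp, drop = FALSE])
    ord <- order(ex$p)
    kept <- integer()
    for (i in ord) {
      if (length(kept)) {
        r2 <- suppressWarnings(
          as.vector(cor(D[, i], D[, kept, drop = FALSE]))^2)
        r2[is.na(r2)] <- 0
        if (any(r2 >= r2Threshold)) next
      }
      kept <- c(kept, i)
    }
    ex <- ex[sort(kept), , drop = FALSE]
  } else if (is.null(ldRef)) {
    mqNote("harmonizeAndSelect: no LD reference supplied; pruning skipped")
  }
  counts["independent"] <- nrow(ex)
  out <- out[match(ex$snp, out$snp), , drop = FALSE]
  ## allele alignment
  same <- ex$ea == out$ea & ex$oa == out$oa
  swapped <- ex$ea == out$oa & ex$oa == out$ea
  out$beta[swapped] <- -out$beta[swapped]
  out$eaf[swapped] <- 1 - out$eaf[swapped]
  keep <- same | swapped
  if (any(!keep))
    mqNote("harmonizeAndSelect: dropped %d SNP(s) with irreconcilable alleles",
           sum(!keep))
  ex <- ex[keep, , drop = FALSE]
  out <- out[keep, , drop = FALSE]
  counts["harmonized"] <- nrow(ex)
  ## palindromic filter
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  palin <- comp[ex$ea] == ex$oa
  ambiguous <- palin & ex$eaf >= palindromicWindow[1] &
    ex$eaf <= palindromicWindow[2]
  ex <- ex[!ambiguous, , drop = FALSE]
  out <- out[!ambiguous, , drop = FALSE]
  counts["after_palindromic"] <- nrow(ex)
  if (!nrow(ex))
    stop("zero instruments after filtering; attrition: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  if (any(ex$beta == 0)) {
    drop0 <- ex$beta == 0
    ex <- ex[!drop0, , drop = FALSE]
    out <- out[!drop0, , drop = FALSE]
  }
  ratio <- out$beta / ex$beta
  ratioSe <- out$se / abs(ex$beta)
  data.frame(snp = ex$snp, betaX = ex$beta, seX = ex$se,
             betaY = out$beta, seY = out$se,
             ratio = ratio, ratioSe = ratioSe, weight = 1 / ratioSe^2,
             stringsAsFactors = FALSE)
}

## interpolated 50% point of the ordered ratios under normalized cumulative
## weights (Bowden's weighted-median construction)
weightedMedianPoint <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(r[1])
  k <- max(which(cw < 0.5))
  if (k == length(r)) return(r[length(r)])
  r[k] + (r[k + 1] - r[k]) * (0.5 - cw[k]) / (cw[k + 1] - cw[k])
}

## kernel-density mode of the ratios; bandwidth from the median absolute
## deviation (phi * 1.4826 * MAD * n^(-1/5)), weights normalized
modePoint <- function(ratio, weight, phi = 1) {
  n <- length(ratio)
  if (diff(range(ratio)) < 1e-12) return(ratio[1])
  bw <- phi * mad(ratio) * n^(-0.2)
  if (bw <= 0) bw <- phi * sd(ratio) * n^(-0.2)
  d <- density(ratio, weights = weight / sum(weight), bw = bw, n = 2048)
  d$x[which.max(d$y)]
}

#' Two-sample Mendelian randomization estimate
#'
#' Methods: `ivw` — inverse-variance weighted mean of the Wald ratios,
#' theta = sum(w_j theta_j) / sum(w_j), fixed-effect se = sqrt(1/sum(w_j))
#' (optionally inflated by sqrt(Q/df) when Q/df > 1); `weighted_median` —
#' interpolated 50% point of the ordered ratios under normalized
#' cumulative weights, se by parametric bootstrap; `simple_mode` /
#' `weighted_mode` — mode of a Gaussian-kernel density over the ratios
#' (unweighted / inverse-variance weighted), bandwidth from the median
#' absolute deviation, se by parametric bootstrap. p-values are two-sided
#' normal. Bootstraps are seeded and reproducible.
#'
#' @param instruments instrument table from [harmonizeAndSelect()] (or any
#'   data.frame with betaX, seX, betaY, seY).
#' @param method one of "ivw", "weighted_median", "simple_mode",
#'   "weighted_mode".
#' @param nBoot bootstrap replicates for median/mode SEs (default 1000).
#' @param seed integer RNG seed for the bootstrap.
#' @param phi mode-estimator bandwidth factor (default 1).
#' @param randomEffects if TRUE, inflate the IVW se by sqrt(Q/df) when
#'   Q/df > 1.
#' @return an [MRResult-class]; for IVW the heterogeneity slots carry
#'   Cochran's Q.
#' @export
mrEstimate <- function(instruments, method = c("ivw", "weighted_median",
                                               "simple_mode",
                                               "weighted_mode"),
                       nBoot = 1000L, seed = 1L, phi = 1,
                       randomEffects = FALSE) {
  method <- match.arg(method)
  ins <- as.data.frame(instruments)
  n <- nrow(ins)
  minNeeded <- if (method == "ivw") 1L else 3L
  if (n < minNeeded)
    stop(method, " needs at least ", minNeeded, " instruments (got ", n, ")")
  ratio <- ins$betaY / ins$betaX
  ratioSe <- ins$seY / abs(ins$betaX)
  w <- 1 / ratioSe^2
  hetQ <- hetDf <- hetP <- NA_real_
  if (method == "ivw") {
    est <- sum(w * ratio) / sum(w)
    se <- sqrt(1 / sum(w))
    if (n >= 2) {
      hetQ <- sum(w * (ratio - est)^2)
      hetDf <- n - 1
      hetP <- pchisq(hetQ, df = hetDf, lower.tail = FALSE)
      if (randomEffects && hetQ / hetDf > 1) se <- se * sqrt(hetQ / hetDf)
    }
  } else {
    pointFun <- switch(method,
      weighted_median = function(r, wt) weightedMedianPoint(r, wt),
      simple_mode = function(r, wt) modePoint(r, rep(1, length(r)), phi),
      weighted_mode = function(r, wt) modePoint(r, wt, phi))
    est <- pointFun(ratio, w)
    set.seed(seed)
    boot <- vapply(seq_len(nBoot), function(i) {
      bx <- rnorm(n, ins$betaX, ins$seX)
      by <- rnorm(n, ins$betaY, ins$seY)
      bx[abs(bx) < 1e-12] <- 1e-12
      br <- by / bx
      bw <- (abs(bx) / ins$seY)^2
      pointFun(br, bw)
    }, numeric(1))
    se <- sd(boot)
  }
  p <- if (se > 0) 2 * pnorm(-abs(est / se)) else as.numeric(est == 0)
  new("MRResult", method = method, estimate = est, se = se, p = p,
      nInstruments = as.integer(n), hetQ = hetQ, hetDf = hetDf, hetP = hetP)
}

#' All four MR estimators on one instrument table
#'
#' @inheritParams mrEstimate
#' @return data.frame with one row per method (method, estimate, se, p,
#'   nInstruments).
#' @export
mrAllMethods <- function(instruments, nBoot = 1000L, seed = 1L) {
  methods <- c("ivw", "weighted_median", "simple_mode", "weighted_mode")
  do.call(rbind, lapply(methods, function(m) {
    r <- mrEstimate(instruments, method = m, nBoot = nBoot, seed = seed)
    data.frame(method = m, estimate = r@estimate, se = r@se, p = r@p,
               nInstruments = r@nInstruments, stringsAsFactors = FALSE)
  }))
}

#' Cochran's Q heterogeneity across instruments
#'
#' `Q = sum(w_j (theta_j - theta_ivw)^2)` with inverse-variance weights,
#' chi-square with n - 1 degrees of freedom under homogeneity.
#'
#' @param instruments instrument table (needs betaX, seY or ratio/ratioSe).
#' @return list with `Q`, `df`, `p`.
#' @export
cochranQ <- function(instruments) {
  ins <- as.data.frame(instruments)
  if (nrow(ins) < 2) stop("Cochran's Q needs at least 2 instruments")
  ratio <- ins$betaY / ins$betaX
  ratioSe <- ins$seY / abs(ins$betaX)
  w <- 1 / ratioSe^2
  ivw <- sum(w * ratio) / sum(w)
  Q <- sum(w * (ratio - ivw)^2)
  df <- nrow(ins) - 1
  list(Q = Q, df = df, p = pchisq(Q, df = df, lower.tail = FALSE))
}
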