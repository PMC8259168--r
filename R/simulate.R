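#' Simulate LD-blocked biallelic genotypes
#'
#' Dosages are drawn per SNP under Hardy-Weinberg equilibrium from two latent
#' standard-normal haplotype processes with first-order autoregressive
#' correlation `rho` between adjacent SNPs inside each block and zero
#' correlation across blocks. Thresholding each haplotype at the
#' MAF quantile yields biallelic alleles whose sum is the dosage, giving
#' tunable r-squared between neighbouring SNPs without coalescent machinery.
#' Each block is placed on its own chromosome.
#'
#' @param nSamples number of samples (>= 2).
#' @param blocks list of blocks, each a list with `nSnps`, `mafRange`
#'   (within \[0.05, 0.5\]) and `rho` (adjacent-SNP latent correlation in
#'   \[0, 1)).
#' @param seed integer RNG seed; the output is bit-reproducible.
#' @param posSpacing base-pair spacing between adjacent SNPs (default 5000).
#' @return a [GenotypeMatrix-class].
#' @examples
#' g <- simulateGenotypes(100, list(list(nSnps = 10, mafRange = c(0.1, 0.4),
#'                                       rho = 0.8)), seed = 1)
#' @export
simulateGenotypes <- function(nSamples, blocks, seed, posSpacing = 5000L) {
  if (nSamples < 2) stop("nSamples must be >= 2")
  set.seed(childSeed(seed, 101L))  # module-specific substream
  dosList <- list()
  snpList <- list()
  offset <- 0L
  bases <- c("A", "C", "G", "T")
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    m <- blk$nSnps
    mafRange <- blk$mafRange
    rho <- blk$rho
    if (length(mafRange) != 2 || any(mafRange < 0.05 - 1e-12) ||
        any(mafRange > 0.5 + 1e-12) || mafRange[1] > mafRange[2])
      stop("mafRange must be an interval within [0.05, 0.5] (block ", b, ")")
    if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1) (block ", b, ")")
    mafs <- runif(m, mafRange[1], mafRange[2])
    thr <- qnorm(mafs)
    dos <- matrix(0L, nSamples, m)
    for (h in 1:2) {
      z <- matrix(rnorm(nSamples * m), nSamples, m)
      if (rho > 0 && m > 1) {
        for (j in 2:m) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      }
      dos <- dos + (z < rep(thr, each = nSamples))
    }
    ids <- paste0("rs", b, "_", seq_len(m))
    refalt <- t(vapply(seq_len(m), function(i) sample(bases, 2), character(2)))
    snpList[[b]] <- data.frame(
      id = ids, chrom = paste0("chr", b),
      pos = offset + seq_len(m) * posSpacing,
      ref = refalt[, 1], alt = refalt[, 2], stringsAsFactors = FALSE)
    colnames(dos) <- ids
    dosList[[b]] <- dos
  }
  dosage <- do.call(cbind, dosList)
  storage.mode(dosage) <- "double"
  rownames(dosage) <- paste0("S", seq_len(nSamples))
  GenotypeMatrix(dosage, do.call(rbind, snpList))
}

#' Simulate a log-normal metabolome with planted genetic and covariate effects
#'
#' Each feature is built on a latent log10 scale as a sum of standardized
#' dosage effects, covariate effects and Gaussian noise, scaled so that the
#' expected variance share of the genetic component equals the planted
#' `fraction`, then exponentiated (base 10) so the emitted values are
#' strictly positive and a downstream log transform is meaningful.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param nFeatures number of metabolite features to emit.
#' @param planted data.frame with columns `snp`, `feature`, `fraction`
#'   (variance fraction in (0,1); per-feature fractions must sum below 1).
#' @param covariates optional data.frame with columns age, sex,
#'   contraceptive aligned with the genotype samples; generated when NULL
#'   (age in years, sex and contraceptive coded 0/1).
#' @param covariateEffects optional data.frame (covariate, feature, beta)
#'   of planted covariate effects in feature-SD units.
#' @param seed integer RNG seed.
#' @return list with elements `features` ([FeatureMatrix-class], platform
#'   "GM"), `covariates` (data.frame) and `ledger` ([TruthLedger-class]).
#' @export
simulateMetabolome <- function(genotypes, nFeatures, planted = NULL,
                               covariates = NULL, covariateEffects = NULL,
                               seed = 1L) {
  set.seed(childSeed(seed, 202L))  # decoupled from the genotype stream
  n <- nrow(dosages(genotypes))
  featIds <- paste0("met_", seq_len(nFeatures))
  if (is.null(covariates)) {
    age <- round(pmin(75, pmax(18, rnorm(n, 28, 12))))
    sex <- rbinom(n, 1, 0.55)                   # 1 = female
    contraceptive <- ifelse(sex == 1, rbinom(n, 1, 0.4), 0L)
    covariates <- data.frame(age = age, sex = sex,
                             contraceptive = contraceptive,
                             row.names = rownames(dosages(genotypes)))
  }
  if (is.null(planted))
    planted <- data.frame(snp = character(), feature = character(),
                          fraction = numeric())
  planted <- as.data.frame(planted)
  if (nrow(planted)) {
    if (is.numeric(planted$feature)) planted$feature <- featIds[planted$feature]
    if (!all(planted$snp %in% snpInfo(genotypes)$id))
      stop("planted refers to unknown SNP ids")
    if (!all(planted$feature %in% featIds))
      stop("planted refers to unknown feature ids")
    if (any(planted$fraction <= 0 | planted$fraction >= 1))
      stop("variance fractions must lie in (0, 1)")
    sums <- tapply(planted$fraction, planted$feature, sum)
    if (any(sums >= 1))
      stop("per-feature variance fractions must sum below 1: ",
           paste(names(sums)[sums >= 1], collapse = ", "))
  }
  if (is.null(covariateEffects))
    covariateEffects <- data.frame(covariate = character(),
                                   feature = character(), beta = numeric())
  covariateEffects <- as.data.frame(covariateEffects)
  if (nrow(covariateEffects)) {
    if (is.numeric(covariateEffects$feature))
      covariateEffects$feature <- featIds[covariateEffects$feature]
    if (!all(covariateEffects$covariate %in% names(covariates)))
      stop("covariateEffects refers to unknown covariates")
  }
  G <- zScore(meanImpute(dosages(genotypes)))
  C <- zScore(covariates)
  vals <- matrix(NA_real_, n, nFeatures,
                 dimnames = list(rownames(dosages(genotypes)), featIds))
  snpEff <- list()
  for (j in seq_len(nFeatures)) {
    fid <- featIds[j]
    y <- numeric(n)
    gvar <- 0
    pj <- planted[planted$feature == fid, , drop = FALSE]
    if (nrow(pj)) {
      betas <- sqrt(pj$fraction)
      for (k in seq_len(nrow(pj)))
        y <- y + betas[k] * G[, pj$snp[k]]
      gvar <- sum(pj$fraction)
      snpEff[[fid]] <- data.frame(snp = pj$snp, feature = fid, beta = betas)
    }
    cvar <- 0
    cj <- covariateEffects[covariateEffects$feature == fid, , drop = FALSE]
    if (nrow(cj)) {
      for (k in seq_len(nrow(cj)))
        y <- y + cj$beta[k] * C[, cj$covariate[k]]
      cvar <- sum(cj$beta^2)
    }
    noiseVar <- 1 - gvar - cvar
    if (noiseVar <= 0)
      stop("planted genetic + covariate variance reaches 1 for ", fid)
    y <- y + rnorm(n, sd = sqrt(noiseVar))
    # latent log10 abundance: arbitrary location/scale, variance shares kept
    vals[, j] <- 10^(runif(1, 1, 3) + 0.3 * y)
  }
  ledger <- new("TruthLedger",
    snpEffects = if (length(snpEff)) do.call(rbind, snpEff) else
      data.frame(snp = character(), feature = character(), beta = numeric()),
    covariateEffects = covariateEffects,
    theta = NA_real_, scenario = "",
    targetGeneticVariance = vapply(featIds, function(f)
      sum(planted$fraction[planted$feature == f]), numeric(1)))
  list(features = FeatureMatrix(vals, platform = "GM"),
       covariates = covariates, ledger = ledger)
}

#' Simulate stimulated-cytokine responses driven by metabolites and SNPs
#'
#' Cytokines are linear combinations of standardized source variables
#' (log10 metabolite levels and/or SNP dosages) plus Gaussian noise, a
#' simple stand-in for log-scale cytokine production capacities.
#'
#' @param metabolome a [FeatureMatrix-class] of metabolites (raw positive
#'   scale; log10 is applied internally before standardization).
#' @param genotypes a [GenotypeMatrix-class].
#' @param mapping data.frame with columns `source` (metabolite feature id or
#'   SNP id), `cytokine` (cytokine id) and `beta`.
#' @param noiseSd positive noise standard deviation.
#' @param seed integer RNG seed.
#' @param cytokines optional character vector of cytokine ids to emit
#'   (defaults to the ids in `mapping`, or "cyt_1" when empty).
#' @return list with `features` (a [FeatureMatrix-class], platform
#'   "cytokine") and `mapping` (the planted effects).
#' @export
simulateImmune <- function(metabolome, genotypes, mapping = NULL,
                           noiseSd = 1, seed = 1L, cytokines = NULL) {
  if (noiseSd <= 0) stop("noiseSd must be positive")
  set.seed(childSeed(seed, 303L))  # decoupled from upstream generators
  if (is.null(mapping))
    mapping <- data.frame(source = character(), cytokine = character(),
                          beta = numeric())
  mapping <- as.data.frame(mapping)
  M <- zScore(log10(featureValues(metabolome)))
  G <- zScore(meanImpute(dosages(genotypes)))
  known <- c(colnames(M), colnames(G))
  if (nrow(mapping) && !all(mapping$source %in% known))
    stop("unknown source id(s): ",
         paste(setdiff(mapping$source, known), collapse = ", "))
  if (is.null(cytokines))
    cytokines <- if (nrow(mapping)) unique(mapping$cytokine) else "cyt_1"
  n <- nrow(M)
  vals <- matrix(rnorm(n * length(cytokines), sd = noiseSd), n,
                 length(cytokines),
                 dimnames = list(rownames(M), cytokines))
  for (k in seq_len(nrow(mapping))) {
    src <- mapping$source[k]
    x <- if (src %in% colnames(M)) M[, src] else G[, src]
    vals[, mapping$cytokine[k]] <- vals[, mapping$cytokine[k]] +
      mapping$beta[k] * x
  }
  list(features = FeatureMatrix(vals, platform = "cytokine"),
       mapping = mapping)
}

#' Simulate a paired exposure/outcome GWAS summary-statistics region
#'
#' Per-SNP effect estimates are drawn analytically around their true values
#' with standard error `1/sqrt(2 eaf (1-eaf) n)` (unit-variance trait),
#' rather than by simulating two full cohorts. Under `shared_causal` the
#' causal SNPs act on both traits with outcome effect `theta` times the
#' exposure effect; `distinct_causal` places different causal SNPs in the
#' two traits; `null` places none.
#'
#' @param scenario "null", "shared_causal" or "distinct_causal".
#' @param mSnps number of SNPs in the region (>= 1).
#' @param nExposure,nOutcome GWAS sample sizes (>= 100).
#' @param theta causal effect (outcome units per exposure SD); must be 0 for
#'   the null scenario.
#' @param seed integer RNG seed.
#' @param nCausal number of causal SNPs (default 1).
#' @param varExplained per-causal-SNP exposure variance explained
#'   (default 0.003).
#' @return list with `exposure` and `outcome` ([SummaryStats-class]) and
#'   `ledger` ([TruthLedger-class]).
#' @export
simulateGwasPair <- function(scenario = c("null", "shared_causal",
                                          "distinct_causal"),
                             mSnps, nExposure, nOutcome, theta = 0,
                             seed = 1L, nCausal = 1L, varExplained = 0.003) {
  scenario <- match.arg(scenario)
  if (mSnps < 1) stop("mSnps must be >= 1")
  if (nExposure < 100 || nOutcome < 100) stop("sample sizes must be >= 100")
  if (scenario == "null" && theta != 0)
    stop("theta must be 0 under the null scenario")
  set.seed(childSeed(seed, 404L))
  eaf <- runif(mSnps, 0.05, 0.5)
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  al <- pairs[sample(nrow(pairs), mSnps, replace = TRUE), , drop = FALSE]
  betaTrueX <- numeric(mSnps)
  betaTrueY <- numeric(mSnps)
  causalX <- integer(0)
  causalY <- integer(0)
  perAllele <- function(idx) sqrt(varExplained / (2 * eaf[idx] * (1 - eaf[idx])))
  if (scenario == "shared_causal") {
    causalX <- sample(mSnps, nCausal)
    causalY <- causalX
    betaTrueX[causalX] <- perAllele(causalX) * sample(c(-1, 1), nCausal, TRUE)
    betaTrueY[causalX] <- theta * betaTrueX[causalX]
  } else if (scenario == "distinct_causal") {
    if (mSnps < 2 * nCausal) stop("mSnps too small for distinct causal SNPs")
    pick <- sample(mSnps, 2 * nCausal)
    causalX <- pick[seq_len(nCausal)]
    causalY <- pick[nCausal + seq_len(nCausal)]
    betaTrueX[causalX] <- perAllele(causalX) * sample(c(-1, 1), nCausal, TRUE)
    betaTrueY[causalY] <- perAllele(causalY) * sample(c(-1, 1), nCausal, TRUE)
  }
  seX <- 1 / sqrt(2 * eaf * (1 - eaf) * nExposure)
  seY <- 1 / sqrt(2 * eaf * (1 - eaf) * nOutcome)
  betaX <- rnorm(mSnps, betaTrueX, seX)
  betaY <- rnorm(mSnps, betaTrueY, seY)
  mk <- function(beta, se, n) {
    SummaryStats(data.frame(
      snp = paste0("rs", seq_len(mSnps)), chrom = "chr1",
      pos = seq_len(mSnps) * 1000L,
      ea = al[, 1], oa = al[, 2], eaf = eaf, beta = beta, se = se,
      p = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin), n = n,
      stringsAsFactors = FALSE))
  }
  causalIdx <- c(causalX, causalY)
  ledger <- new("TruthLedger",
    snpEffects = data.frame(
      snp = if (length(causalIdx)) paste0("rs", causalIdx) else character(),
      feature = rep(c("exposure", "outcome"),
                    c(length(causalX), length(causalY))),
      beta = c(betaTrueX[causalX], betaTrueY[causalY])),
    covariateEffects = data.frame(covariate = character(),
                                  feature = character(), beta = numeric()),
    theta = theta, scenario = scenario,
    targetGeneticVariance = numeric())
  list(exposure = mk(betaX, seX, nExposure),
       outcome = mk(betaY, seY, nOutcome),
       ledger = ledger)
}

#' Paper-like genetic-variance fractions preset
#'
#' Returns 49 per-feature genetic variance fractions spanning 0.013 to 0.676
#' on a geometric grid with the middle value pinned at 0.081, emulating the
#' reported spread of metabolite heritability-like fractions (range about
#' 1.3-67.6%, median 8.1%).
#'
#' @return sorted numeric vector of length 49 with median 0.081.
#' @export
paperLikeFractions <- function() {
  lower <- exp(seq(log(0.013), log(0.081), length.out = 25))
  upper <- exp(seq(log(0.081), log(0.676), length.out = 25))
  sort(c(lower[-25], 0.081, upper[-1]))
}
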