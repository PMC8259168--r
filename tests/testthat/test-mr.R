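test_that("harmonization aligns alleles, flips swapped rows, drops palindromes", {
  ex <- suppressWarnings(SummaryStats(data.frame(
    snp = c("rs1", "rs2", "rs3"), ea = c("A", "C", "A"),
    oa = c("G", "T", "T"), eaf = c(0.3, 0.2, 0.5),
    beta = c(0.5, 0.4, 0.3), se = c(0.02, 0.02, 0.02),
    p = c(1e-100, 1e-80, 1e-50), n = 50000)))
  out <- suppressWarnings(SummaryStats(data.frame(
    snp = c("rs1", "rs2", "rs3"), ea = c("G", "C", "A"),
    oa = c("A", "T", "T"), eaf = c(0.7, 0.2, 0.5),
    beta = c(-0.05, 0.04, 0.03), se = c(0.01, 0.01, 0.01),
    p = c(1e-6, 1e-4, 1e-3), n = 50000)))
  ins <- suppressMessages(harmonizeAndSelect(ex, out, ldRef = NULL))
  # rs1 swapped: outcome beta sign flipped; rs3 palindromic at eaf 0.5: gone
  expect_setequal(ins$snp, c("rs1", "rs2"))
  expect_equal(ins$betaY[ins$snp == "rs1"], 0.05)
  expect_equal(ins$ratio[ins$snp == "rs1"], 0.1)
})

test_that("LD pruning keeps the best exposure p among correlated candidates", {
  set.seed(1)
  n <- 1000
  a <- rbinom(n, 2, 0.3)
  d <- cbind(rs1 = a, rs2 = a, rs3 = rbinom(n, 2, 0.3))
  rownames(d) <- paste0("S", 1:n)
  ldRef <- GenotypeMatrix(d, data.frame(id = colnames(d), chrom = "chr1",
                                        pos = 1:3, ref = "A", alt = "G"))
  mk <- function(p) SummaryStats(data.frame(
    snp = colnames(d), ea = "A", oa = "G", eaf = 0.3,
    beta = c(0.5, 0.45, 0.4), se = 0.02, p = p, n = 50000))
  ex <- suppressWarnings(mk(c(1e-120, 1e-100, 1e-90)))
  out <- suppressWarnings(SummaryStats(data.frame(
    snp = colnames(d), ea = "A", oa = "G", eaf = 0.3,
    beta = c(0.05, 0.045, 0.04), se = 0.01, p = 1e-5, n = 50000)))
  ins <- harmonizeAndSelect(ex, out, ldRef = ldRef)
  expect_setequal(ins$snp, c("rs1", "rs3"))
})

test_that("single-instrument IVW is the Wald ratio; consensus is exact", {
  one <- makeInstruments(betaX = 0.4, betaY = -0.028, seY = 0.01)
  r <- mrEstimate(one, "ivw")
  expect_equal(r@estimate, -0.07, tolerance = 1e-12)

  # identical ratios: every method returns theta, Q = 0
  bx <- c(0.3, 0.4, 0.5, 0.6)
  ins <- makeInstruments(bx, -0.07 * bx, seY = rep(0.01, 4))
  for (m in c("ivw", "weighted_median", "simple_mode", "weighted_mode")) {
    est <- mrEstimate(ins, m, nBoot = 50)@estimate
    expect_equal(est, -0.07, tolerance = 1e-10)
  }
  q <- cochranQ(ins)
  expect_equal(q$Q, 0, tolerance = 1e-20)
  expect_equal(q$p, 1)
})

test_that("IVW equals the weighted-least-squares-through-origin oracle", {
  ins <- makeInstruments(betaX = c(0.2, 0.5, 0.8),
                         betaY = c(0.01, 0.04, 0.05),
                         seY = c(0.01, 0.02, 0.015))
  r <- mrEstimate(ins, "ivw")
  # oracle: WLS of betaY on betaX through the origin, weights 1/seY^2
  oracle <- lm(betaY ~ 0 + betaX, data = ins, weights = 1 / seY^2)
  expect_equal(r@estimate, unname(coef(oracle)), tolerance = 1e-10)
})

test_that("Cochran's Q matches hand arithmetic", {
  # ratios 1 and 2 with unit weights: IVW 1.5, Q = 0.5, df = 1
  ins <- makeInstruments(betaX = c(1, 1), betaY = c(1, 2), seY = c(1, 1))
  q <- cochranQ(ins)
  expect_equal(q$Q, 0.5)
  expect_equal(q$df, 1)
  expect_equal(q$p, pchisq(0.5, 1, lower.tail = FALSE))
  expect_error(cochranQ(ins[1, ]), "at least 2")
})

test_that("estimates are invariant to allele-coding sign flips", {
  set.seed(2)
  ins <- makeInstruments(betaX = runif(8, 0.2, 0.6),
                         betaY = runif(8, -0.05, 0.01),
                         seY = runif(8, 0.005, 0.02))
  flip <- ins
  flip$betaX[c(2, 5)] <- -flip$betaX[c(2, 5)]
  flip$betaY[c(2, 5)] <- -flip$betaY[c(2, 5)]
  for (m in c("ivw", "weighted_median", "simple_mode", "weighted_mode")) {
    expect_equal(mrEstimate(ins, m, nBoot = 100, seed = 3)@estimate,
                 mrEstimate(flip, m, nBoot = 100, seed = 3)@estimate,
                 tolerance = 1e-9)
  }
})

test_that("weighted median with equal weights is the plain median", {
  for (k in c(5, 6)) {
    set.seed(k)
    bx <- rep(1, k)
    by <- rnorm(k)
    ins <- makeInstruments(bx, by, seY = rep(0.5, k))
    est <- mrEstimate(ins, "weighted_median", nBoot = 50)@estimate
    expect_equal(est, median(by), tolerance = 1e-10)
  }
})

test_that("all four methods recover theta = -0.07 from 8 strong instruments", {
  pair <- simulateGwasPair("shared_causal", mSnps = 400, nExposure = 50000,
                           nOutcome = 50000, theta = -0.07, seed = 8,
                           nCausal = 8, varExplained = 0.05)
  ins <- suppressMessages(
    harmonizeAndSelect(pair$exposure, pair$outcome, ldRef = NULL))
  expect_equal(nrow(ins), 8)
  tab <- mrAllMethods(ins, seed = 8)
  expect_true(all(abs(tab$estimate - (-0.07)) < 0.02))
  # concordance: all four agree in sign and scale
  expect_true(all(tab$estimate < 0))
})

test_that("IVW is unbiased over repeated shared-causal draws", {
  ests <- vapply(1:60, function(s) {
    pair <- simulateGwasPair("shared_causal", mSnps = 100, nExposure = 50000,
                             nOutcome = 50000, theta = -0.07, seed = 4000 + s,
                             nCausal = 8, varExplained = 0.05)
    ins <- suppressMessages(
      harmonizeAndSelect(pair$exposure, pair$outcome, ldRef = NULL))
    mrEstimate(ins, "ivw")@estimate
  }, numeric(1))
  expect_lt(abs(mean(ests) + 0.07), 0.01)
})

test_that("weighted median tolerates 30% pleiotropic instruments; IVW breaks", {
  set.seed(5)
  k <- 10
  bx <- runif(k, 0.3, 0.6)
  by <- -0.07 * bx
  by[1:3] <- by[1:3] + 0.15 * bx[1:3]   # constant pleiotropic offset
  ins <- makeInstruments(bx, by, seY = rep(1e-4, k))
  wm <- mrEstimate(ins, "weighted_median", nBoot = 200)@estimate
  ivw <- mrEstimate(ins, "ivw")@estimate
  expect_lt(abs(wm - (-0.07)), 0.02)
  expect_gte(abs(ivw - (-0.07)), 0.03)
})

test_that("Cochran's Q type-I error is near nominal under homogeneity", {
  rejections <- 0
  reps <- 200
  for (s in seq_len(reps)) {
    set.seed(6000 + s)
    k <- 8
    bxTrue <- runif(k, 0.3, 0.6)
    seX <- rep(0.01, k)
    seY <- rep(0.01, k)
    ins <- makeInstruments(rnorm(k, bxTrue, seX),
                           rnorm(k, -0.07 * bxTrue, seY), seY = seY,
                           seX = seX)
    if (cochranQ(ins)$p < 0.05) rejections <- rejections + 1
  }
  expect_lt(abs(rejections / reps - 0.05), 0.03)
})

test_that("method preconditions are enforced by instrument count", {
  one <- makeInstruments(0.5, 0.05, 0.01)
  expect_error(mrEstimate(one, "weighted_median"), "at least 3")
  expect_error(mrEstimate(one[0, ], "ivw"), "at least 1")
})
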