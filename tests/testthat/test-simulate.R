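test_that("genotype simulation respects MAF targets, HWE and determinism", {
  g <- simulateGenotypes(10000, list(
    list(nSnps = 20, mafRange = c(0.5, 0.5), rho = 0)), seed = 1)
  emp <- colMeans(dosages(g)) / 2
  expect_true(all(abs(emp - 0.5) < 0.02))

  g2 <- simulateGenotypes(10000, list(
    list(nSnps = 20, mafRange = c(0.5, 0.5), rho = 0)), seed = 1)
  expect_identical(dosages(g), dosages(g2))
  expect_identical(snpInfo(g), snpInfo(g2))

  # HWE holds by construction: exact test should not reject grossly
  d <- dosages(g)[, 1]
  expect_gt(hweExactTest(sum(d == 0), sum(d == 1), sum(d == 2)), 1e-4)
})

test_that("AR(1) blocks create within-block LD but no cross-block LD", {
  g <- simulateGenotypes(2000, list(
    list(nSnps = 10, mafRange = c(0.2, 0.4), rho = 0.9),
    list(nSnps = 10, mafRange = c(0.2, 0.4), rho = 0.9)), seed = 2)
  d <- dosages(g)
  adjacentR2 <- function(cols) {
    sapply(seq_len(length(cols) - 1), function(i)
      cor(d[, cols[i]], d[, cols[i + 1]])^2)
  }
  within <- c(adjacentR2(1:10), adjacentR2(11:20))
  crossPairs <- expand.grid(a = 1:10, b = 11:20)
  cross <- mapply(function(a, b) cor(d[, a], d[, b])^2,
                  crossPairs$a, crossPairs$b)
  expect_gt(mean(within), mean(cross))
  expect_lt(mean(cross), 0.01)
})

test_that("genotype simulation rejects invalid parameters by name", {
  expect_error(simulateGenotypes(100, list(
    list(nSnps = 5, mafRange = c(0.01, 0.3), rho = 0)), seed = 1), "mafRange")
  expect_error(simulateGenotypes(100, list(
    list(nSnps = 5, mafRange = c(0.1, 0.3), rho = 1)), seed = 1), "rho")
  expect_error(simulateGenotypes(1, list(
    list(nSnps = 5, mafRange = c(0.1, 0.3), rho = 0)), seed = 1), "nSamples")
})

test_that("planted metabolite variance fractions are realized", {
  g <- simulateGenotypes(5000, list(
    list(nSnps = 5, mafRange = c(0.2, 0.4), rho = 0)), seed = 3)
  sim <- simulateMetabolome(g, 3, planted = data.frame(
    snp = snpInfo(g)$id[1], feature = "met_1", fraction = 0.08), seed = 3)
  vals <- featureValues(sim$features)
  expect_true(all(vals > 0))
  y <- log10(vals[, "met_1"])
  r2 <- summary(lm(y ~ dosages(g)[, 1]))$r.squared
  expect_lt(abs(r2 - 0.08), 0.02)
  expect_equal(sim$ledger@targetGeneticVariance[["met_1"]], 0.08)
})

test_that("metabolome generator rejects over-planted features", {
  g <- smallGenotypes()
  expect_error(simulateMetabolome(g, 2, planted = data.frame(
    snp = snpInfo(g)$id[1:2], feature = c("met_1", "met_1"),
    fraction = c(0.6, 0.5)), seed = 1), "sum below 1")
})

test_that("unplanted features give uniform QTL scan p-values", {
  g <- simulateGenotypes(500, list(
    list(nSnps = 100, mafRange = c(0.1, 0.5), rho = 0)), seed = 4)
  sim <- simulateMetabolome(g, 10, planted = NULL, seed = 4)
  met <- logTransform(sim$features)
  scan <- qtlScan(g, met)
  ks <- ks.test(scan$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("cytokine simulation is a faithful linear readout of its sources", {
  g <- smallGenotypes(n = 500)
  sim <- simulateMetabolome(g, 5, seed = 5)
  # monotone limit: tiny noise makes source and cytokine rank-identical
  imm <- simulateImmune(sim$features, g,
                        mapping = data.frame(source = "met_2",
                                             cytokine = "cyt_1", beta = 1),
                        noiseSd = 1e-6, seed = 5)
  rho <- cor(rank(log10(featureValues(sim$features)[, "met_2"])),
             rank(featureValues(imm$features)[, "cyt_1"]))
  expect_gt(rho, 0.999)

  imm2 <- simulateImmune(sim$features, g,
                         mapping = data.frame(source = "met_2",
                                              cytokine = "cyt_1", beta = 1),
                         noiseSd = 1e-6, seed = 5)
  expect_identical(featureValues(imm$features), featureValues(imm2$features))

  expect_error(simulateImmune(sim$features, g,
                              mapping = data.frame(source = "nope",
                                                   cytokine = "c", beta = 1),
                              noiseSd = 1, seed = 1), "unknown source")
})

test_that("null cytokines show no metabolite associations at FDR 0.05", {
  # BH permits a ~5% chance of a stray discovery per scan: require a clean
  # grid in at least 2 of 3 independent replicates
  clean <- 0
  for (s in 6:8) {
    g <- smallGenotypes(n = 500, seed = s)
    sim <- simulateMetabolome(g, 20, seed = s)
    imm <- simulateImmune(sim$features, g, mapping = NULL, noiseSd = 1,
                          seed = s, cytokines = paste0("cyt_", 1:5))
    met <- logTransform(sim$features)
    tab <- adjustedSpearmanScan(met, imm$features,
                                covariates = sim$covariates)
    if (all(tab$q > 0.05, na.rm = TRUE)) clean <- clean + 1
  }
  expect_gte(clean, 2)
})

test_that("gwas pair scenarios carry their planted structure", {
  expect_error(simulateGwasPair("null", 10, 1000, 1000, theta = 0.1, seed = 1),
               "theta")
  pair <- simulateGwasPair("shared_causal", 50, 10000, 10000, theta = -0.5,
                           seed = 1)
  expect_s4_class(pair$exposure, "SummaryStats")
  led <- pair$ledger
  expect_identical(led@scenario, "shared_causal")
  # same causal SNP in both traits, outcome beta = theta * exposure beta
  eff <- led@snpEffects
  expect_identical(eff$snp[eff$feature == "exposure"],
                   eff$snp[eff$feature == "outcome"])
  expect_equal(eff$beta[eff$feature == "outcome"],
               -0.5 * eff$beta[eff$feature == "exposure"])
  pair2 <- simulateGwasPair("shared_causal", 50, 10000, 10000, theta = -0.5,
                            seed = 1)
  expect_identical(sumStats(pair$exposure), sumStats(pair2$exposure))
})

test_that("paper-like fraction preset spans the reported range with median 8.1%", {
  f <- paperLikeFractions()
  expect_equal(median(f), 0.081)
  expect_equal(min(f), 0.013)
  expect_equal(max(f), 0.676)
})
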