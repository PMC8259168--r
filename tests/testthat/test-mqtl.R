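test_that("fast-path t equals the full multiple-regression t", {
  set.seed(1)
  n <- 120
  g <- smallGenotypes(n = n, seed = 1)
  cov <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("m", 1:3)))
  scan <- qtlScan(g, y, covariates = cov)
  for (i in sample(nrow(scan), 10)) {
    snp <- dosages(g)[, scan$snp[i]]
    fit <- summary(lm(y[, scan$feature[i]] ~ snp + cov$age + cov$sex))
    expect_equal(scan$t[i], fit$coefficients["snp", "t value"],
                 tolerance = 1e-6)
    expect_equal(scan$beta[i], fit$coefficients["snp", "Estimate"],
                 tolerance = 1e-8)
    expect_equal(scan$p[i], fit$coefficients["snp", "Pr(>|t|)"],
                 tolerance = 1e-6)
  }
})

test_that("planted-beta confidence intervals reach nominal coverage", {
  covered <- 0
  reps <- 400
  for (s in seq_len(reps)) {
    set.seed(1000 + s)
    n <- 2000
    maf <- 0.3
    dos <- rbinom(n, 2, maf)
    betaTrue <- sqrt(0.1 / (2 * maf * (1 - maf)))  # variance fraction 0.1
    y <- betaTrue * dos + rnorm(n, sd = sqrt(1 - 0.1))
    g <- GenotypeMatrix(matrix(dos, ncol = 1,
                               dimnames = list(paste0("S", 1:n), "rs1")),
                        data.frame(id = "rs1", chrom = "chr1", pos = 1,
                                   ref = "A", alt = "G"))
    scan <- qtlScan(g, matrix(y, ncol = 1, dimnames = list(NULL, "m")))
    ci <- scan$beta + c(-1.96, 1.96) * scan$se
    if (betaTrue >= ci[1] && betaTrue <= ci[2]) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.93)
})

test_that("scan p-values are uniform under permuted features", {
  set.seed(2)
  g <- simulateGenotypes(500, list(
    list(nSnps = 100, mafRange = c(0.1, 0.5), rho = 0)), seed = 2)
  y <- matrix(rnorm(500 * 100), 500, 100,
              dimnames = list(NULL, paste0("m", 1:100)))
  scan <- qtlScan(g, y)   # 10^4 null pairs
  expect_gt(ks.test(scan$p, "punif")$p.value, 0.01)
})

test_that("Bonferroni thresholds reproduce the platform cut-offs", {
  expect_equal(signif(bonferroniThreshold(5e-8, 231), 3), 2.16e-10)
  expect_equal(signif(bonferroniThreshold(5e-8, 1589), 3), 3.15e-11)
  expect_equal(signif(bonferroniThreshold(5e-8, 8614), 3), 5.80e-12)
  expect_equal(signif(bonferroniThreshold(5e-8, 231 + 1589 + 8614), 2), 4.8e-12)
  expect_equal(bonferroniThreshold(5e-8, 1), 5e-8)
  expect_error(bonferroniThreshold(5e-8, 0), "mFeatures")
})

test_that("clumping follows the greedy lead-absorb definition", {
  # hand-built dosages: A and B in perfect LD, C independent
  set.seed(3)
  n <- 200
  a <- rbinom(n, 2, 0.3)
  cSnp <- rbinom(n, 2, 0.3)
  d <- cbind(A = a, B = a, C = cSnp)
  rownames(d) <- paste0("S", 1:n)
  g <- GenotypeMatrix(d, data.frame(id = colnames(d), chrom = "chr1",
                                    pos = c(100, 200, 300), ref = "A",
                                    alt = "G"))
  rec <- data.frame(snp = c("A", "B", "C"), feature = "m",
                    p = c(1e-12, 1e-10, 1e-8))
  loci <- clumpLoci(rec, g)
  expect_length(loci, 2)
  expect_identical(loci[[1]]$lead, "A")
  expect_setequal(loci[[1]]$members, c("A", "B"))
  expect_identical(loci[[2]]$members, "C")
  # partition: every SNP in exactly one locus
  all <- unlist(lapply(loci, `[[`, "members"))
  expect_setequal(all, c("A", "B", "C"))
  expect_identical(anyDuplicated(all), 0L)

  expect_error(clumpLoci(data.frame(snp = "X", feature = "m", p = 0.1), g),
               "absent")
})

test_that("chained LD assigns members to the strongest eligible lead", {
  # A-B r2 = 0.5, B-C r2 = 0.5, A-C r2 ~ 0, p(A) < p(B) < p(C):
  # greedy gives {A, B} then {C}
  set.seed(4)
  n <- 4000
  # latent correlations: A-B = B-C = 0.7, A-C = 0 (PSD, eigenvalues > 0)
  R <- rbind(c(1, 0.7, 0), c(0.7, 1, 0.7), c(0, 0.7, 1))
  lat <- matrix(rnorm(n * 3), n, 3) %*% chol(R)
  d <- apply(lat, 2, function(x) as.numeric(cut(x, breaks = c(-Inf,
    qnorm(0.25), qnorm(0.75), Inf))) - 1)
  colnames(d) <- c("A", "B", "C")
  rownames(d) <- paste0("S", 1:n)
  r2AB <- cor(d[, "A"], d[, "B"])^2
  r2BC <- cor(d[, "B"], d[, "C"])^2
  r2AC <- cor(d[, "A"], d[, "C"])^2
  expect_gt(r2AB, 0.1); expect_gt(r2BC, 0.1); expect_lt(r2AC, 0.1)
  g <- GenotypeMatrix(d, data.frame(id = colnames(d), chrom = "chr1",
                                    pos = c(100, 200, 300), ref = "A",
                                    alt = "G"))
  rec <- data.frame(snp = c("A", "B", "C"), feature = "m",
                    p = c(1e-12, 1e-10, 1e-8))
  loci <- clumpLoci(rec, g)
  expect_length(loci, 2)
  expect_setequal(loci[[1]]$members, c("A", "B"))
  expect_identical(loci[[2]]$members, "C")
})

test_that("genetic variance recovers a planted fraction and handles no leads", {
  set.seed(5)
  n <- 5000
  g <- simulateGenotypes(n, list(
    list(nSnps = 5, mafRange = c(0.2, 0.4), rho = 0)), seed = 5)
  sim <- simulateMetabolome(g, 1, planted = data.frame(
    snp = snpInfo(g)$id[1], feature = "met_1", fraction = 0.08), seed = 5)
  met <- logTransform(sim$features)
  gv <- geneticVariance(featureValues(met)[, 1], snpInfo(g)$id[1], g,
                        covariates = sim$covariates)
  expect_lt(abs(gv$adjR2 - 0.08), 0.02)
  expect_equal(geneticVariance(rnorm(100), character(),
                               smallGenotypes(100))$adjR2, 0)
})
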