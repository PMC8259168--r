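test_that("rank invariance: monotone transforms give rho = 1", {
  set.seed(1)
  a <- matrix(rnorm(50), ncol = 1, dimnames = list(NULL, "a"))
  b <- matrix(exp(a[, 1]) + a[, 1]^3, ncol = 1, dimnames = list(NULL, "b"))
  tab <- adjustedSpearmanScan(a, b)
  expect_equal(tab$rho, 1)
})

test_that("BH adjustment matches the brute-force step-up rule", {
  set.seed(2)
  for (i in 1:5) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, method = "BH"), bhStepUp(p), tolerance = 1e-12)
  }
  # and the scan's q column uses exactly that family
  a <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("a", 1:10)))
  b <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("b", 1:5)))
  tab <- adjustedSpearmanScan(a, b)
  expect_equal(tab$q, bhStepUp(tab$p), tolerance = 1e-12)
  expect_true(all(tab$q >= tab$p))
})

test_that("adjusted Spearman equals plain Spearman under constant covariates", {
  set.seed(3)
  a <- matrix(rnorm(100), ncol = 2, dimnames = list(NULL, c("a1", "a2")))
  b <- matrix(rnorm(100), ncol = 2, dimnames = list(NULL, c("b1", "b2")))
  plain <- adjustedSpearmanScan(a, b)
  adj <- suppressMessages(
    adjustedSpearmanScan(a, b, covariates = data.frame(x = rep(2, 50))))
  expect_equal(adj$rho, plain$rho, tolerance = 1e-12)
  expect_equal(adj$p, plain$p, tolerance = 1e-12)
})

test_that("covariate adjustment removes confounder-driven correlation", {
  set.seed(4)
  n <- 500
  conf <- rnorm(n)
  a <- matrix(conf + rnorm(n, sd = 0.5), ncol = 1, dimnames = list(NULL, "a"))
  b <- matrix(conf + rnorm(n, sd = 0.5), ncol = 1, dimnames = list(NULL, "b"))
  raw <- adjustedSpearmanScan(a, b)
  adj <- adjustedSpearmanScan(a, b, covariates = data.frame(conf = conf))
  expect_gt(raw$rho, 0.6)
  expect_lt(abs(adj$rho), 0.15)
})

test_that("planted association is recovered with q < 0.05", {
  set.seed(5)
  n <- 500
  x <- rnorm(n)
  a <- matrix(c(x, rnorm(n)), ncol = 2, dimnames = list(NULL, c("sig", "null")))
  b <- matrix(0.5 * scale(x) + sqrt(1 - 0.25) * rnorm(n), ncol = 1,
              dimnames = list(NULL, "y"))
  tab <- adjustedSpearmanScan(a, b)
  sig <- tab[tab$feature_a == "sig", ]
  expect_lt(abs(sig$rho - 0.5), 0.1)
  expect_lt(sig$q, 0.05)
})

test_that("fully null scans rarely produce any BH discovery", {
  clean <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    a <- matrix(rnorm(500 * 20), 500, 20,
                dimnames = list(NULL, paste0("a", 1:20)))
    b <- matrix(rnorm(500 * 5), 500, 5,
                dimnames = list(NULL, paste0("b", 1:5)))
    tab <- adjustedSpearmanScan(a, b)
    if (sum(tab$q < 0.05, na.rm = TRUE) == 0) clean <- clean + 1
  }
  expect_gte(clean, 17)  # BH FWER-like behaviour under the global null
})

test_that("pairs below the minimum n or with zero variance are undefined", {
  a <- matrix(c(1:5, rep(NA, 15)), ncol = 1, dimnames = list(NULL, "a"))
  b <- matrix(rnorm(20), ncol = 1, dimnames = list(NULL, "b"))
  tab <- adjustedSpearmanScan(a, b)
  expect_true(is.na(tab$p))
  aZero <- matrix(rep(1, 20), ncol = 1, dimnames = list(NULL, "z"))
  tabZ <- adjustedSpearmanScan(aZero, b)
  expect_true(is.na(tabZ$rho))
})

test_that("host-factor scan summarizes significance and sign correctly", {
  set.seed(6)
  n <- 300
  sex <- rbinom(n, 1, 0.5)
  feats <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("f", 1:10)))
  # plant positive sex effects on features 1-3
  for (j in 1:3) feats[, j] <- feats[, j] + 1.2 * sex
  hf <- hostFactorScan(FeatureMatrix(feats),
                       data.frame(sex = sex, noise = rnorm(n)))
  s <- hf$summary
  expect_equal(s$fractionSignificant[s$factor == "sex"], 0.3, tolerance = 0.11)
  expect_equal(s$fractionPositive[s$factor == "sex"], 1)
  expect_lt(s$fractionSignificant[s$factor == "noise"], 0.05)
  # factor equal to a feature: rho = 1, q tiny
  hf2 <- hostFactorScan(FeatureMatrix(cbind(f1 = sex + 0)),
                        data.frame(sex = sex))
  expect_equal(hf2$assoc$rho, 1)
})

test_that("clustering groups correlated blocks and is order-invariant", {
  # two perfectly anti-correlated blocks of rho-vectors
  rho <- rbind(a1 = c(1, 1, -1, -1), a2 = c(1, 1, -1, -1),
               b1 = c(-1, -1, 1, 1), b2 = c(-1, -1, 1, 1))
  colnames(rho) <- paste0("c", 1:4)
  cl <- clusterCorrelationMatrix(rho)
  ord <- cl$rowOrder
  expect_true(which(ord == "a1") %in%
                c(which(ord == "a2") - 1, which(ord == "a2") + 1))
  expect_true(abs(which(ord == "b1") - which(ord == "b2")) == 1)

  # permuting input rows leaves the 2-cluster partition unchanged
  perm <- c(3, 1, 4, 2)
  cl2 <- clusterCorrelationMatrix(rho[perm, ])
  part1 <- cutree(cl$rowHclust, k = 2)
  part2 <- cutree(cl2$rowHclust, k = 2)[names(part1)]
  expect_true(all(outer(part1, part1, "==") == outer(part2, part2, "==")))

  single <- clusterCorrelationMatrix(rho[1, , drop = FALSE])
  expect_identical(single$rowOrder, "a1")
})
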