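# small fixtures built in code, shared across test files

smallGenotypes <- function(n = 200, seed = 11) {
  simulateGenotypes(n, list(
    list(nSnps = 20, mafRange = c(0.1, 0.5), rho = 0.5)), seed = seed)
}

# brute-force step-up BH: the oracle for p.adjust(method = "BH")
bhStepUp <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- prev
  }
  q
}

# brute-force coloc: explicit enumeration over all single-causal and
# ordered two-causal SNP configurations
colocEnumerate <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  m <- length(labf1)
  b1 <- exp(labf1)
  b2 <- exp(labf2)
  w0 <- 1
  w1 <- p1 * sum(b1)
  w2 <- p2 * sum(b2)
  w3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) w3 <- w3 + p1 * p2 * b1[i] * b2[j]
  }
  w4 <- p12 * sum(b1 * b2)
  w <- c(w0, w1, w2, w3, w4)
  setNames(w / sum(w), c("H0", "H1", "H2", "H3", "H4"))
}

# instrument table with exact planted ratios and precision
makeInstruments <- function(betaX, betaY, seY, seX = rep(1e-3, length(betaX))) {
  data.frame(snp = paste0("rs", seq_along(betaX)), betaX = betaX, seX = seX,
             betaY = betaY, seY = seY,
             ratio = betaY / betaX, ratioSe = seY / abs(betaX),
             weight = (abs(betaX) / seY)^2, stringsAsFactors = FALSE)
}
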