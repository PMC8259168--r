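#' Training-data predictor selection for cytokine prediction
#'
#' SNP predictors are those with a marginal association to the cytokine at
#' p < `snpP` (additive linear model, as in the QTL scan); metabolite
#' predictors are those with adjusted-Spearman p < `metabP`. Both screens
#' run on the training rows only — the cross-validation driver enforces
#' that no held-out row is touched. An empty SNP set is allowed (the model
#' degenerates to the intercept, logged by the driver).
#'
#' @param trainGenotypes [GenotypeMatrix-class] (training rows).
#' @param trainMetabolites [FeatureMatrix-class] (training rows, log10
#'   scale).
#' @param trainCytokine numeric cytokine vector (training rows).
#' @param snpP SNP selection threshold (default 5e-5).
#' @param metabP metabolite selection threshold (default 0.001, the
#'   metabolite feature-class threshold).
#' @param covariates optional covariate data.frame (training rows).
#' @return list with `snps` and `metabolites` (character id vectors).
#' @export
selectPredictors <- function(trainGenotypes, trainMetabolites, trainCytokine,
                             snpP = 5e-5, metabP = 0.001, covariates = NULL) {
  y <- matrix(trainCytokine, ncol = 1, dimnames = list(NULL, "cytokine"))
  qs <- qtlScan(trainGenotypes, y, covariates = covariates)
  snps <- qs$snp[qs$p < snpP]
  ms <- adjustedSpearmanScan(trainMetabolites, y, covariates = covariates)
  mets <- ms$feature_a[!is.na(ms$p) & ms$p < metabP]
  list(snps = snps, metabolites = mets)
}

#' Repeated 2-fold cross-validated elastic-net model comparison
#'
#' For each cytokine: covariates are regressed out, then for each of
#' `nRepeats` seeded repeats the samples are split into `kFolds` folds.
#' Within each training fold, predictors are selected (nested, training
#' rows only) and two elastic-net models are fitted (mixing `alphaMix`,
#' penalty chosen by internal cross-validation): SNPs only, and SNPs plus
#' metabolites. Prediction accuracy is the Spearman correlation between
#' held-out measured and predicted values; the split indices are identical
#' across the two model tags (paired design). A paired two-sided t-test
#' over the per-split rho values compares the models per cytokine, with BH
#' adjustment across cytokines.
#'
#' @param genotypes [GenotypeMatrix-class].
#' @param metabolites [FeatureMatrix-class] (log10 scale).
#' @param cytokines [FeatureMatrix-class] of cytokine responses.
#' @param covariates optional covariate data.frame.
#' @param nRepeats repeats (default 10).
#' @param kFolds folds per repeat (default 2).
#' @param alphaMix elastic-net mixing parameter (default 0.5).
#' @param seed integer RNG seed controlling the splits and fits.
#' @param snpP,metabP nested selection thresholds (see
#'   [selectPredictors()]).
#' @return list with `perSplit` (data.frame: cytokine, repeat_, fold,
#'   model, rho), `comparison` (per-cytokine paired t, p, q and mean rho
#'   per model) and `skipped` (constant cytokines).
#' @export
cvCompare <- function(genotypes, metabolites, cytokines, covariates = NULL,
                      nRepeats = 10L, kFolds = 2L, alphaMix = 0.5,
                      seed = 1L, snpP = 5e-5, metabP = 0.001) {
  G <- meanImpute(dosages(genotypes))
  M <- featureValues(metabolites)
  Y <- featureValues(cytokines)
  n <- nrow(G)
  stopifnot(nrow(M) == n, nrow(Y) == n)
  X <- covariateDesign(covariates, n)
  Yres <- residualizeColumns(Y, X)
  perSplit <- list()
  skipped <- character()
  for (cyt in colnames(Y)) {
    y <- Yres[, cyt]
    if (sd(y, na.rm = TRUE) < 1e-12) {
      skipped <- c(skipped, cyt)
      mqNote("cvCompare: skipped constant cytokine %s", cyt)
      next
    }
    for (rep_ in seq_len(nRepeats)) {
      set.seed(childSeed(seed, rep_))
      foldId <- sample(rep(seq_len(kFolds), length.out = n))
      for (fold in seq_len(kFolds)) {
        test <- foldId == fold
        train <- !test
        gTrain <- new("GenotypeMatrix",
                      dosage = G[train, , drop = FALSE],
                      snps = snpInfo(genotypes))
        mTrain <- FeatureMatrix(M[train, , drop = FALSE],
                                platform = platform(metabolites))
        sel <- selectPredictors(gTrain, mTrain, y[train],
                                snpP = snpP, metabP = metabP)
        for (model in c("snp_only", "snp_plus_metabolite")) {
          cols <- G[, sel$snps, drop = FALSE]
          if (model == "snp_plus_metabolite")
            cols <- cbind(cols, M[, sel$metabolites, drop = FALSE])
          rho <- fitPredictRho(cols, y, train, test, alphaMix,
                               childSeed(seed, rep_ * 100 + fold))
          perSplit[[length(perSplit) + 1L]] <- data.frame(
            cytokine = cyt, repeat_ = rep_, fold = fold, model = model,
            rho = rho, stringsAsFactors = FALSE)
        }
      }
    }
  }
  perSplit <- do.call(rbind, perSplit)
  comparison <- NULL
  if (!is.null(perSplit)) {
    comparison <- do.call(rbind, lapply(unique(perSplit$cytokine),
                                        function(cyt) {
      sub <- perSplit[perSplit$cytokine == cyt, ]
      key <- paste(sub$repeat_, sub$fold)
      a <- sub$rho[sub$model == "snp_only"][order(key[sub$model == "snp_only"])]
      b <- sub$rho[sub$model == "snp_plus_metabolite"][
        order(key[sub$model == "snp_plus_metabolite"])]
      tt <- if (sd(b - a) < 1e-12) {
        ## both models identical on every split: no evidence of a difference
        list(statistic = 0, p.value = 1)
      } else {
        t.test(b, a, paired = TRUE)
      }
      data.frame(cytokine = cyt, meanRhoSnp = mean(a), meanRhoBoth = mean(b),
                 deltaRho = mean(b - a), t = unname(tt$statistic),
                 p = tt$p.value, stringsAsFactors = FALSE)
    }))
    comparison$q <- p.adjust(comparison$p, method = "BH")
  }
  list(perSplit = perSplit, comparison = comparison, skipped = skipped)
}

## elastic-net fit on the training rows, Spearman rho on held-out rows;
## an empty predictor set degenerates to the intercept (rho recorded as 0)
fitPredictRho <- function(cols, y, train, test, alphaMix, seed) {
  ok <- is.finite(y)
  train <- train & ok
  test <- test & ok
  if (is.null(cols) || ncol(cols) < 2) {
    ## glmnet needs >= 2 columns; with 0-1 predictors fall back to OLS
    if (is.null(cols) || ncol(cols) == 0) {
      pred <- rep(mean(y[train]), sum(test))
    } else {
      fit <- lm(y[train] ~ cols[train, 1])
      pred <- coef(fit)[1] + coef(fit)[2] * cols[test, 1]
    }
  } else {
    set.seed(seed)
    cvfit <- glmnet::cv.glmnet(cols[train, , drop = FALSE], y[train],
                               alpha = alphaMix, nfolds = 5)
    pred <- as.vector(predict(cvfit, cols[test, , drop = FALSE],
                              s = "lambda.min"))
  }
  if (sd(pred) == 0 || sd(y[test]) == 0) return(0)
  cor(rank(pred), rank(y[test]))
}
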