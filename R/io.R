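#' Read a genotype matrix from VCF or TSV
#'
#' VCF ingest (4.x) prefers the DS (dosage) FORMAT field when present and
#' otherwise converts GT calls 0/0, 0/1, 1/1 (or phased variants) to dosages
#' 0, 1, 2; missing calls become missing dosages and are excluded from MAF.
#' Multi-allelic records are skipped (not split) with a logged count. The
#' TSV dialect is a tab-delimited samples x SNPs matrix with a `sample`
#' first column; per-SNP metadata travels in a companion `<path>.snps` file
#' written by [writeGenotypeMatrix()] (placeholder metadata is synthesized
#' when the companion file is absent).
#'
#' @param path file path.
#' @param format "vcf" or "tsv".
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypeMatrix <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(tab)[1] != "sample")
      stop("genotype TSV must have a 'sample' first column")
    dosage <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(dosage) <- "double"
    rownames(dosage) <- tab$sample
    metaPath <- paste0(path, ".snps")
    if (file.exists(metaPath)) {
      snps <- read.delim(metaPath, stringsAsFactors = FALSE)
    } else {
      mqNote("no SNP metadata companion for %s; synthesizing placeholders", path)
      snps <- data.frame(id = colnames(dosage), chrom = "chrU",
                         pos = seq_len(ncol(dosage)), ref = "N", alt = "N",
                         stringsAsFactors = FALSE)
    }
    return(GenotypeMatrix(dosage, snps))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  bial <- !grepl(",", fix$ALT, fixed = TRUE)
  if (any(!bial))
    mqNote("skipped %d multi-allelic VCF record(s)", sum(!bial))
  if (!any(bial)) stop("no biallelic records in ", path)
  v <- v[bial, ]
  fix <- fix[bial, , drop = FALSE]
  hasDS <- any(grepl("(^|:)DS(:|$)", v@gt[, "FORMAT"]))
  if (hasDS) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    dosage <- t(ds)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    cnt <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("|", "/", gt, fixed = TRUE)
    cnt[clean == "0/0"] <- 0
    cnt[clean %in% c("0/1", "1/0")] <- 1
    cnt[clean == "1/1"] <- 2
    badRows <- which(rowSums(!is.na(gt) & is.na(cnt)) > 0)
    if (length(badRows))
      stop("malformed GT at VCF record(s): ",
           paste(head(badRows, 5), collapse = ", "))
    dosage <- t(cnt)
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  colnames(dosage) <- ids
  snps <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  GenotypeMatrix(dosage, snps)
}

#' Write a genotype matrix as TSV (dosage + SNP metadata companion)
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output path for the dosage TSV; metadata goes to
#'   `<path>.snps`.
#' @return invisibly, `path`.
#' @export
writeGenotypeMatrix <- function(g, path) {
  tab <- data.frame(sample = sampleIds(g), dosages(g), check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(snpInfo(g), paste0(path, ".snps"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Hardy-Weinberg exact test on genotype counts
#'
#' Two-sided exact test: the p-value is the sum of the conditional
#' probabilities (given the allele counts) of all heterozygote counts at
#' most as probable as the observed one.
#'
#' @param nAA,nAa,naa genotype counts.
#' @return exact two-sided p-value.
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  if (n == 0) return(NA_real_)
  hetPossible <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  ## log conditional probability of each heterozygote count given nA
  logProb <- vapply(hetPossible, function(h) {
    hom1 <- (nA - h) / 2
    hom2 <- n - h - hom1
    lfactorial(n) - lfactorial(hom1) - lfactorial(h) - lfactorial(hom2) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  }, numeric(1))
  prob <- exp(logProb - logSumExp(logProb))
  obs <- prob[hetPossible == nAa]
  min(1, sum(prob[prob <= obs + 1e-12]))
}

#' Filter variants on minor-allele frequency and Hardy-Weinberg equilibrium
#'
#' Dosages are rounded to \{0, 1, 2\} (non-missing entries) for the exact
#' HWE test. SNPs with MAF below `mafMin` or exact-test HWE p below
#' `hweAlpha` are removed; removal counts are logged.
#'
#' @param g a [GenotypeMatrix-class].
#' @param mafMin MAF threshold (default 0.05).
#' @param hweAlpha HWE exact-test significance threshold (default 1e-4).
#' @return the filtered [GenotypeMatrix-class] (possibly with zero SNPs).
#' @export
filterVariants <- function(g, mafMin = 0.05, hweAlpha = 1e-4) {
  d <- dosages(g)
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  mafFail <- is.na(maf) | maf < mafMin
  hweP <- vapply(seq_len(ncol(d)), function(j) {
    x <- round(d[, j])
    x <- x[is.finite(x)]
    hweExactTest(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  hweFail <- !is.na(hweP) & hweP < hweAlpha
  keep <- !mafFail & !hweFail
  mqNote("filterVariants: removed %d/%d SNPs (%d MAF < %g, %d HWE p < %g)",
         sum(!keep), ncol(d), sum(mafFail), mafMin, sum(hweFail & !mafFail),
         hweAlpha)
  new("GenotypeMatrix", dosage = d[, keep, drop = FALSE],
      snps = snpInfo(g)[keep, , drop = FALSE])
}

#' Read GWAS summary statistics from TSV
#'
#' Canonical dialect: tab-delimited with header columns snp, ea, oa, eaf,
#' beta, se, p, n (chrom, pos optional); `columnMap` renames non-canonical
#' headers on ingest. Rows with se <= 0 or eaf outside (0,1) are rejected
#' with a logged row-level report; allele columns are upper-cased.
#'
#' @param path file path.
#' @param traitType "quantitative" or "case_control".
#' @param columnMap optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(snp = "rsid")`.
#' @return a [SummaryStats-class].
#' @export
readSummaryStats <- function(path, traitType = "quantitative",
                             columnMap = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(columnMap)) {
    for (canon in names(columnMap)) {
      j <- match(columnMap[[canon]], names(tab))
      if (!is.na(j)) names(tab)[j] <- canon
    }
  }
  need <- c("snp", "ea", "oa", "eaf", "beta", "se", "p", "n")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  bad <- tab$se <= 0 | tab$eaf <= 0 | tab$eaf >= 1 | !is.finite(tab$beta)
  if (any(bad)) {
    mqNote("readSummaryStats: rejected %d row(s) (rows %s)", sum(bad),
           paste(head(which(bad), 10), collapse = ", "))
    tab <- tab[!bad, , drop = FALSE]
  }
  if (!nrow(tab)) stop("no valid rows in ", path)
  SummaryStats(tab, traitType = traitType)
}

#' Write GWAS summary statistics as TSV
#' @param s a [SummaryStats-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeSummaryStats <- function(s, path) {
  write.table(sumStats(s), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write feature matrices as TSV (samples as rows)
#'
#' @param path file path.
#' @param platform platform tag for the returned object.
#' @return a [FeatureMatrix-class].
#' @export
readFeatureMatrix <- function(path, platform = "other") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample")
    stop("feature TSV must have a 'sample' first column")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- tab$sample
  FeatureMatrix(vals, platform = platform)
}

#' @rdname readFeatureMatrix
#' @param m a [FeatureMatrix-class].
#' @export
writeFeatureMatrix <- function(m, path) {
  tab <- data.frame(sample = sampleIds(m), featureValues(m),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP annotation BED file
#'
#' BED intervals (0-based half-open) are converted to 1-based inclusive
#' coordinates on ingest. Column 4 is the class label (exonic, intronic,
#' 3'UTR, 5'UTR, gene, ...); column 5, when present, a gene id.
#'
#' @param path BED file path.
#' @return a `GRanges` with metadata columns `class` and `gene`.
#' @export
readSnpAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("annotation BED needs at least 4 columns")
  gr <- GenomicRanges::GRanges(
    seqnames = tab[[1]],
    ranges = IRanges::IRanges(start = tab[[2]] + 1L, end = tab[[3]]))
  S4Vectors::mcols(gr)$class <- tab[[4]]
  S4Vectors::mcols(gr)$gene <- if (ncol(tab) >= 5) tab[[5]] else NA_character_
  gr
}
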