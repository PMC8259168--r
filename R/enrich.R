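#' Annotate SNPs with functional classes and nearby genes
#'
#' Positional overlap on 1-based inclusive coordinates (BED input is
#' converted on ingest by [readSnpAnnotation()]). When a SNP overlaps
#' several class intervals the priority order exonic > 5'UTR > 3'UTR >
#' intronic is applied; SNPs overlapping nothing are "intergenic". A SNP is
#' assigned to a gene when it falls within the gene body extended by
#' `geneWindowBp` on both sides. SNPs on chromosomes absent from the
#' annotation are labelled "unannotated" and counted.
#'
#' @param snps data.frame with columns id, chrom, pos (e.g. from
#'   [snpInfo()]).
#' @param annotation `GRanges` with metadata columns `class` and `gene`
#'   (class "gene" rows define gene bodies).
#' @param geneWindowBp gene-assignment window (default 10000).
#' @return data.frame (id, class, gene).
#' @export
annotateSnps <- function(snps, annotation, geneWindowBp = 10000) {
  stopifnot(all(c("id", "chrom", "pos") %in% names(snps)))
  known <- as.character(GenomicRanges::seqnames(annotation))
  onKnown <- snps$chrom %in% known
  if (any(!onKnown))
    mqNote("annotateSnps: %d SNP(s) on chromosomes absent from the annotation",
           sum(!onKnown))
  cls <- rep("intergenic", nrow(snps))
  cls[!onKnown] <- "unannotated"
  gene <- rep(NA_character_, nrow(snps))
  if (any(onKnown)) {
    q <- GenomicRanges::GRanges(
      seqnames = snps$chrom[onKnown],
      ranges = IRanges::IRanges(start = snps$pos[onKnown], width = 1L))
    annCls <- annotation[S4Vectors::mcols(annotation)$class != "gene"]
    priority <- c("exonic", "5'UTR", "3'UTR", "intronic")
    hits <- GenomicRanges::findOverlaps(q, annCls)
    if (length(hits)) {
      hitCls <- S4Vectors::mcols(annCls)$class[S4Vectors::subjectHits(hits)]
      rank <- match(hitCls, priority)
      rank[is.na(rank)] <- length(priority) + 1L
      best <- tapply(seq_along(rank), S4Vectors::queryHits(hits),
                     function(ii) ii[which.min(rank[ii])])
      idx <- as.integer(names(best))
      cls[which(onKnown)[idx]] <- hitCls[unlist(best)]
    }
    annGene <- annotation[S4Vectors::mcols(annotation)$class == "gene"]
    if (length(annGene)) {
      wide <- GenomicRanges::resize(annGene,
                                    GenomicRanges::width(annGene) +
                                      2 * geneWindowBp, fix = "center")
      gh <- GenomicRanges::findOverlaps(q, wide)
      if (length(gh)) {
        first <- tapply(S4Vectors::subjectHits(gh), S4Vectors::queryHits(gh),
                        `[`, 1L)
        idx <- as.integer(names(first))
        gene[which(onKnown)[idx]] <-
          S4Vectors::mcols(annGene)$gene[unlist(first)]
      }
    }
  }
  data.frame(id = snps$id, class = cls, gene = gene,
             stringsAsFactors = FALSE)
}

#' Permutation-based functional-class enrichment
#'
#' Draws `nPerm` same-sized SNP sets without replacement from the
#' background pool (variants with no significant association), counts each
#' functional class per draw to form a null distribution, and reports the
#' add-one empirical p-value `(1 + #(null >= observed)) / (nPerm + 1)` per
#' class, so p is never zero and its floor at 1000 permutations is 1/1001.
#'
#' @param target annotated target SNPs: character vector of class labels or
#'   a data.frame with a `class` column (e.g. from [annotateSnps()]).
#' @param background annotated background pool, same form; must be at least
#'   as large as the target.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer RNG seed.
#' @return data.frame (class, observed, nullMean, nullSd, p).
#' @export
permutationEnrichment <- function(target, background, nPerm = 1000L,
                                  seed = 1L) {
  asClasses <- function(x) if (is.data.frame(x)) x$class else as.character(x)
  tgt <- asClasses(target)
  bg <- asClasses(background)
  if (length(bg) < length(tgt))
    stop("background (", length(bg), ") smaller than target (", length(tgt), ")")
  bg <- sort(bg)  # draws depend on the class multiset, not input order
  set.seed(seed)
  classes <- sort(unique(c(tgt, bg)))
  observed <- vapply(classes, function(cl) sum(tgt == cl), numeric(1))
  nullCounts <- matrix(0, nPerm, length(classes),
                       dimnames = list(NULL, classes))
  for (i in seq_len(nPerm)) {
    draw <- bg[sample.int(length(bg), length(tgt))]
    t0 <- table(draw)
    nullCounts[i, names(t0)] <- as.numeric(t0)
  }
  p <- vapply(seq_along(classes), function(j)
    (1 + sum(nullCounts[, j] >= observed[j])) / (nPerm + 1), numeric(1))
  data.frame(class = classes, observed = observed,
             nullMean = colMeans(nullCounts),
             nullSd = apply(nullCounts, 2, sd), p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher-exact overlap of mQTLs with a trait catalog, height as reference
#'
#' Builds the 2x2 table
#' \[\[|mqtl n trait|, |trait \\ mqtl|\], \[|mqtl n height|, |height \\ mqtl|\]\]
#' and tests one-sided (greater) whether the trait catalog overlaps the
#' mQTL set more than the height catalog does. When neither catalog
#' overlaps the mQTL set the odds ratio is undefined and reported as NA
#' with p = 1.
#'
#' @param mqtlSnps character vector of mQTL SNP ids.
#' @param traitCatalog,heightCatalog character vectors of catalog SNP ids
#'   (non-empty).
#' @return list with `table`, `oddsRatio`, `p`.
#' @export
catalogOverlapFisher <- function(mqtlSnps, traitCatalog, heightCatalog) {
  if (!length(traitCatalog) || !length(heightCatalog))
    stop("trait and height catalogs must be non-empty")
  mqtlSnps <- unique(mqtlSnps)
  a <- length(intersect(mqtlSnps, traitCatalog))
  b <- length(setdiff(traitCatalog, mqtlSnps))
  c_ <- length(intersect(mqtlSnps, heightCatalog))
  d <- length(setdiff(heightCatalog, mqtlSnps))
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("trait", "height"),
                                c("in_mqtl", "not_in_mqtl")))
  if (a == 0 && c_ == 0)
    return(list(table = tab, oddsRatio = NA_real_, p = 1))
  ft <- fisher.test(tab, alternative = "greater")
  list(table = tab, oddsRatio = unname(ft$estimate), p = ft$p.value)
}
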