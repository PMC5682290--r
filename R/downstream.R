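# Region-set enrichment folds, translation-efficiency ratios, rank-overlap
# enrichment and up/down-regulation contrasts.

#' @importFrom stats quantile median sd prop.test
#' @importFrom GenomicRanges reduce countOverlaps findOverlaps
NULL

#' Density-fold enrichment between two region sets
#'
#' \code{fold = (n1/size1) / (n2/size2)}: the per-base feature density of
#' set 1 relative to set 2, with a two-sided Fisher exact p-value on the
#' site-versus-base 2x2 table (binomial alternative by flag).
#'
#' @param n1,size1 feature count and total genomic size (bases) of set 1.
#' @param n2,size2 same for set 2.
#' @param test \code{"fisher"} (default) or \code{"binomial"}.
#' @return list with \code{fold}, \code{p}, the four inputs, and an
#'   \code{infinite} flag when \code{n2 == 0}.
#' @export
regionEnrichment <- function(n1, size1, n2, size2,
                             test = c("fisher", "binomial")) {
    test <- match.arg(test)
    if (size1 <= 0 || size2 <= 0) stop("region sizes must be positive")
    fold <- (n1 / size1) / (n2 / size2)
    p <- if (n2 == 0 || n1 == 0) {
        NA_real_
    } else if (test == "fisher") {
        fisher.test(matrix(c(n1, size1 - n1, n2, size2 - n2), nrow = 2L,
                           byrow = TRUE))$p.value
    } else {
        stats::binom.test(n1, n1 + n2,
                          p = size1 / (size1 + size2))$p.value
    }
    list(fold = fold, p = p, n1 = n1, size1 = size1, n2 = n2, size2 = size2,
         infinite = n2 == 0)
}

#' Count features overlapping a merged region set
#'
#' Regions are merged (overlaps collapsed) before counting; point or
#' interval features are counted once per occurrence.
#'
#' @param features a \linkS4class{GRanges} of features (duplicates count
#'   separately).
#' @param regions a \linkS4class{GRanges} region set.
#' @param ignoreStrand count overlaps irrespective of strand (default TRUE).
#' @return list with \code{n} (features overlapping) and \code{size}
#'   (total merged region size in bases).
#' @export
countFeaturesInRegions <- function(features, regions, ignoreStrand = TRUE) {
    merged <- reduce(regions, ignore.strand = ignoreStrand)
    hits <- countOverlaps(features, merged, ignore.strand = ignoreStrand)
    list(n = sum(hits > 0), size = sum(GenomicRanges::width(merged)))
}

# library-size normalisers for count vectors (genes x samples handled
# per-column by the callers)
.normalizeCounts <- function(mat, method = c("total", "median-ratio")) {
    method <- match.arg(method)
    mat <- as.matrix(mat)
    if (method == "total") {
        tot <- colSums(mat)
        if (any(tot == 0)) stop("library with zero total")
        sweep(mat, 2L, mean(tot) / tot, `*`)
    } else {
        # median-of-ratios: size factor = median of per-gene ratios to the
        # geometric mean across libraries (genes with any zero excluded)
        lg <- log(mat)
        ok <- is.finite(rowSums(lg))
        if (!any(ok)) stop("no gene with positive counts in all libraries")
        ref <- rowMeans(lg[ok, , drop = FALSE])
        sf <- apply(lg[ok, , drop = FALSE], 2L,
                    function(col) exp(median(col - ref)))
        sweep(mat, 2L, sf, `/`)
    }
}

#' Normalized per-gene fold change between conditions
#'
#' \code{FC = normalized count (KD) / normalized count (control)} with a
#' total-count (default) or median-of-ratios library normalizer.
#'
#' @param countsKD,countsControl named per-gene count vectors.
#' @param normalizer \code{"total"} or \code{"median-ratio"}.
#' @return data.frame with gene, normalized counts, \code{fc}
#'   (NA, flagged, when both counts are zero; Inf when only control is 0).
#' @export
foldChange <- function(countsKD, countsControl,
                       normalizer = c("total", "median-ratio")) {
    genes <- intersect(names(countsKD), names(countsControl))
    m <- cbind(KD = countsKD[genes], control = countsControl[genes])
    nm <- .normalizeCounts(m, normalizer)
    fc <- ifelse(nm[, "KD"] == 0 & nm[, "control"] == 0, NA_real_,
                 nm[, "KD"] / nm[, "control"])
    data.frame(gene = genes, normKD = nm[, "KD"],
               normControl = nm[, "control"], fc = fc,
               undefined = nm[, "KD"] == 0 & nm[, "control"] == 0,
               zeroControl = nm[, "control"] == 0 & nm[, "KD"] > 0,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Translation efficiency and its knockdown-to-control ratio
#'
#' TE = normalized Ribo-seq count / normalized RNA-seq count per condition;
#' TER = TE(KD) / TE(control), which is identically the ratio of the
#' Ribo-seq and RNA-seq fold changes.  Only genes with strictly more than
#' \code{minReads} raw reads in both assays (summed over conditions) are
#' retained.
#'
#' @param riboKD,riboControl,rnaKD,rnaControl named per-gene count vectors.
#' @param minReads coverage filter (default 100, strict).
#' @param normalizer library normalizer, see \code{\link{foldChange}}.
#' @return data.frame with per-gene TE per condition, fcRibo, fcRna and
#'   \code{ter}; the identity \code{ter == fcRibo/fcRna} holds to numerical
#'   precision.
#' @export
translationEfficiency <- function(riboKD, riboControl, rnaKD, rnaControl,
                                  minReads = 100L,
                                  normalizer = c("total", "median-ratio")) {
    genes <- Reduce(intersect, list(names(riboKD), names(riboControl),
                                    names(rnaKD), names(rnaControl)))
    riboTot <- riboKD[genes] + riboControl[genes]
    rnaTot <- rnaKD[genes] + rnaControl[genes]
    keep <- riboTot > minReads & rnaTot > minReads
    genes <- genes[keep]
    if (!length(genes)) stop("no gene passes the coverage filter")
    fcR <- foldChange(riboKD[genes], riboControl[genes], normalizer)
    fcN <- foldChange(rnaKD[genes], rnaControl[genes], normalizer)
    teC <- fcR$normControl / fcN$normControl
    teK <- fcR$normKD / fcN$normKD
    data.frame(gene = genes, teControl = teC, teKD = teK,
               fcRibo = fcR$fc, fcRna = fcN$fc, ter = teK / teC,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Enrichment of a feature set among the top of a ranked list
#'
#' Builds the 2x2 table of membership in the top \code{topN} of the ranked
#' list against membership in the feature versus background set; the fold
#' is the ratio of top-list rates.
#'
#' @param ranked character vector of gene ids, best first; must contain
#'   every gene of both sets.
#' @param featureSet,backgroundSet character vectors (disjoint gene sets).
#' @param topN size of the head of the list (default 1000).
#' @return list with \code{fold}, Fisher \code{p} and the 2x2 table.
#' @export
rankOverlapEnrichment <- function(ranked, featureSet, backgroundSet,
                                  topN = 1000L) {
    if (topN > length(ranked)) stop("topN exceeds the ranked list length")
    top <- ranked[seq_len(topN)]
    a <- sum(featureSet %in% top); c_ <- length(featureSet) - a
    b <- sum(backgroundSet %in% top); d <- length(backgroundSet) - b
    rateF <- a / (a + c_); rateB <- b / (b + d)
    fold <- if (rateB == 0) ifelse(rateF == 0, NaN, Inf) else rateF / rateB
    tab <- matrix(c(a, b, c_, d), nrow = 2L,
                  dimnames = list(c("feature", "background"),
                                  c("top", "rest")))
    list(fold = fold, p = fisher.test(tab)$p.value, table = tab)
}

#' Up- versus down-regulation contrast between two gene sets
#'
#' Per set, the fractions of genes up- (FC > 1) and downregulated (FC < 1),
#' optionally restricted by a significance mask, with a 2x2 Fisher exact
#' test of up/down composition between the sets.
#'
#' @param setA,setB character vectors of gene ids.
#' @param fc named fold-change vector covering both sets.
#' @param significant optional named logical mask; genes not significant
#'   count as unchanged.
#' @return list with per-set fractions, the 2x2 table and Fisher \code{p}.
#' @export
updownContrast <- function(setA, setB, fc, significant = NULL) {
    if (!length(setA) || !length(setB)) stop("empty gene set")
    status <- function(genes) {
        v <- fc[genes]
        sig <- if (is.null(significant)) rep(TRUE, length(v))
               else significant[genes] %in% TRUE
        up <- sum(v > 1 & sig, na.rm = TRUE)
        down <- sum(v < 1 & sig, na.rm = TRUE)
        c(up = up, down = down, n = length(genes))
    }
    a <- status(setA); b <- status(setB)
    tab <- matrix(c(a["up"], b["up"], a["down"], b["down"]), nrow = 2L,
                  dimnames = list(c("setA", "setB"), c("up", "down")))
    p <- if (any(rowSums(tab) == 0)) NA_real_ else fisher.test(tab)$p.value
    list(fractions = data.frame(
             set = c("A", "B"),
             up = c(a["up"] / a["n"], b["up"] / b["n"]),
             down = c(a["down"] / a["n"], b["down"] / b["n"])),
         table = tab, p = p)
}
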