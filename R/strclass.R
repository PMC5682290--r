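# Per-base DS/SS classification and transcript-level stability summaries.

#' @importFrom stats dhyper fisher.test wilcox.test p.adjust
NULL

# Two-sided exact p for the 2x2 table [a, b; n1-a, n2-b], conditioning on
# all margins (the classical 2x2 Fisher construction): sums hypergeometric
# point masses no larger than the observed one (with fisher.test's relative
# slack for ties).  Vectorised over bases for whole-transcriptome scans;
# stats::fisher.test is the cross-check in the test suite.
.exactTestTwoSided <- function(a, b, n1, n2) {
    vapply(seq_along(a), function(i) {
        k <- a[i] + b[i]
        if (k == 0) return(1)
        lo <- max(0L, k - n2); hi <- min(n1, k)
        d <- dhyper(lo:hi, n1, n2, k)
        sum(d[d <= d[a[i] - lo + 1L] * (1 + 1e-7)])
    }, 0)
}

#' Classify each base as DS, SS or undetermined
#'
#' For base \code{j}, a two-sided exact test on the 2x2 table
#' \code{[v1[j], s1[j]; V1total - v1[j], S1total - s1[j]]} (counts rounded
#' half-to-even to integers) compares the base's share of V1 read starts
#' with its share of S1 read starts.  A base is DS when significant and
#' V1-enriched, SS when significant and S1-enriched, otherwise
#' undetermined.
#'
#' @param v1,s1 normalized per-base read-start vectors of one transcript.
#' @param alpha significance level (default 0.05).
#' @param fdr when TRUE, Benjamini-Hochberg-adjusted p-values are used for
#'   the call (off by default).
#' @return data.frame with columns \code{class} ("DS"/"SS"/"undetermined")
#'   and \code{p}.
#' @export
classifyBases <- function(v1, s1, alpha = 0.05, fdr = FALSE) {
    if (length(v1) != length(s1)) stop("track lengths differ")
    a <- as.integer(round(v1)); b <- as.integer(round(s1))
    n1 <- sum(a); n2 <- sum(b)
    if (n1 == 0 || n2 == 0) stop("zero total read starts in a track")
    p <- .exactTestTwoSided(a, b, n1, n2)
    padj <- if (fdr) p.adjust(p, "BH") else p
    cls <- rep("undetermined", length(a))
    enrV1 <- a / n1 > b / n2
    enrS1 <- a / n1 < b / n2
    # p rounded to 12 significant digits before the alpha comparison, so
    # tables whose exact p IS the threshold (e.g. 1/20) classify
    # consistently regardless of summation order
    sig <- signif(padj, 12) <= alpha
    cls[sig & enrV1] <- "DS"
    cls[sig & enrS1] <- "SS"
    data.frame(class = cls, p = p, stringsAsFactors = FALSE)
}

#' Transcripts eligible for structure-ratio analysis
#'
#' Retains transcripts strictly longer than \code{minLength} bases and
#' covered by strictly more than \code{minReadStarts} raw read starts summed
#' over all samples.
#'
#' @param x a \linkS4class{ParsExperiment}.
#' @param minLength length threshold (default 100).
#' @param minReadStarts coverage threshold (default 256).
#' @return character vector of transcript ids.
#' @export
eligibleTranscripts <- function(x, minLength = 100L, minReadStarts = 256L) {
    lens <- transcriptLengths(x)
    tots <- rowsum(rowSums(assay(x, "counts")), rowData(x)$transcript)
    tots <- tots[names(lens), 1L]
    names(lens)[lens > minLength & tots > minReadStarts]
}

#' Summarize base calls into a DS/(DS+SS) ratio
#'
#' @param calls data.frame from \code{\link{classifyBases}}.
#' @return list with \code{nDS}, \code{nSS}, \code{nUndetermined},
#'   \code{ratio} (NA, flagged \code{undefined}, when no base is confidently
#'   classified).
#' @export
dsRatio <- function(calls) {
    nDS <- sum(calls$class == "DS")
    nSS <- sum(calls$class == "SS")
    list(nDS = nDS, nSS = nSS,
         nUndetermined = sum(calls$class == "undetermined"),
         ratio = if (nDS + nSS > 0) nDS / (nDS + nSS) else NA_real_,
         undefined = nDS + nSS == 0)
}

#' Per-transcript DS/(DS+SS) ratios for every sample pair
#'
#' Runs \code{\link{classifyBases}} on the V1/S1 track pair of each
#' condition and replicate for the requested transcripts.
#'
#' @param x a normalized \linkS4class{ParsExperiment}.
#' @param transcripts transcript ids (default: all eligible at the standard
#'   length > 100 / read starts > 256 filter).
#' @param alpha per-base significance level.
#' @return data.frame with columns transcript, condition, replicate, nDS,
#'   nSS, ratio.
#' @export
dsRatioByTranscript <- function(x, transcripts = eligibleTranscripts(x),
                                alpha = 0.05) {
    cd <- colData(x)
    out <- list()
    for (tx in transcripts) {
        m <- trackMatrix(x, tx)
        for (cond in unique(cd$condition)) {
            for (rep in sort(unique(cd$replicate[cd$condition == cond]))) {
                jV <- which(cd$condition == cond & cd$enzyme == "V1" &
                            cd$replicate == rep)
                jS <- which(cd$condition == cond & cd$enzyme == "S1" &
                            cd$replicate == rep)
                if (length(jV) != 1L || length(jS) != 1L) next
                r <- dsRatio(classifyBases(m[, jV], m[, jS], alpha))
                out[[length(out) + 1L]] <- data.frame(
                    transcript = tx, condition = cond, replicate = rep,
                    nDS = r$nDS, nSS = r$nSS, ratio = r$ratio,
                    stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, out)
}

#' Paired comparison of DS/(DS+SS) ratios between conditions
#'
#' @param control,kd named numeric vectors of per-transcript ratios
#'   (replicate-averaged); names are transcript ids and must match.
#' @return list with the per-transcript deltas (control - KD), the paired
#'   two-sided Wilcoxon signed-rank p-value, and the fraction of transcripts
#'   with control > KD.
#' @export
compareConditions <- function(control, kd) {
    common <- intersect(names(control), names(kd))
    common <- common[!is.na(control[common]) & !is.na(kd[common])]
    if (length(common) < 2L) stop("fewer than 2 matched transcripts")
    delta <- control[common] - kd[common]
    p <- if (all(delta == 0)) 1 else
        wilcox.test(control[common], kd[common], paired = TRUE,
                    exact = FALSE)$p.value
    list(delta = delta, p = p,
         fractionControlHigher = mean(delta > 0),
         n = length(common))
}

#' Classify transcripts as stabilized or destabilized while edited
#'
#' Replicate ratios are averaged per condition; a transcript is DSWE
#' (destabilized while edited) when its mean DS/(DS+SS) ratio is higher in
#' KD than in control — editing was destabilizing the duplex, so losing it
#' restores pairing — and SWE (stabilized while edited) when the control
#' mean is higher.  Exact ties or undefined ratios are unclassified.
#'
#' @param control,kd numeric matrices or vectors of per-replicate ratios,
#'   rows = transcripts (rownames = ids).
#' @return data.frame with columns transcript, meanControl, meanKD, class.
#' @export
classifySWE <- function(control, kd) {
    control <- as.matrix(control); kd <- as.matrix(kd)
    if (nrow(control) != nrow(kd)) stop("transcript sets differ")
    mC <- rowMeans(control, na.rm = TRUE)
    mK <- rowMeans(kd, na.rm = TRUE)
    cls <- rep("unclassified", length(mC))
    ok <- is.finite(mC) & is.finite(mK)
    cls[ok & mK > mC] <- "DSWE"
    cls[ok & mC > mK] <- "SWE"
    data.frame(transcript = if (!is.null(rownames(control)))
                   rownames(control) else as.character(seq_along(mC)),
               meanControl = mC, meanKD = mK, class = cls,
               stringsAsFactors = FALSE, row.names = NULL)
}
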