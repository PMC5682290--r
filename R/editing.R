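# A-to-I editing quantification, differential editing, hyper-edited read
# criteria, and duplex pairing-context analysis.

#' @importFrom stats cor.test
NULL

#' Read a per-site pileup table
#'
#' Tab format with 1-based positions: columns \code{transcript} (or
#' \code{chrom}), \code{pos}, \code{strand}, \code{A}, \code{C}, \code{G},
#' \code{T}.
#'
#' @param path file path.
#' @return data.frame of per-site base counts.
#' @export
readPileup <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    names(df)[names(df) == "chrom"] <- "transcript"
    need <- c("transcript", "pos", "strand", "A", "C", "G", "T")
    if (!all(need %in% names(df)))
        stop("pileup must have columns ", paste(need, collapse = ", "))
    df
}

#' Quantify editing levels at known sites
#'
#' Records A and G counts per condition at each known site (A-to-G changes
#' only; other bases at the site are ignored) and the pooled editing level
#' G/(A+G) per condition.  Sites with zero A+G coverage in both conditions
#' are omitted.
#'
#' @param pileups data.frame with columns transcript, pos, strand,
#'   condition, replicate, A, C, G, T (e.g. \code{\link{simulatePileups}}
#'   output, or stacked \code{\link{readPileup}} tables with condition and
#'   replicate columns added).
#' @param sites data.frame of known sites with columns transcript, pos,
#'   strand.
#' @return data.frame with per-condition A/G counts and levels per site.
#' @export
callEditing <- function(pileups, sites) {
    if (is.null(sites$strand) || any(is.na(sites$strand)))
        stop("site strand is required")
    out <- list()
    for (i in seq_len(nrow(sites))) {
        sel <- pileups$transcript == sites$transcript[i] &
            pileups$pos == sites$pos[i] &
            pileups$strand == sites$strand[i]
        if (!any(sel)) next
        p <- pileups[sel, ]
        agg <- function(cond, basecol)
            sum(p[[basecol]][p$condition == cond])
        aC <- agg("control", "A"); gC <- agg("control", "G")
        aK <- agg("KD", "A"); gK <- agg("KD", "G")
        if (aC + gC + aK + gK == 0) next
        out[[length(out) + 1L]] <- data.frame(
            transcript = sites$transcript[i], pos = sites$pos[i],
            strand = sites$strand[i],
            aControl = aC, gControl = gC, aKD = aK, gKD = gK,
            levelControl = if (aC + gC > 0) gC / (aC + gC) else NA_real_,
            levelKD = if (aK + gK > 0) gK / (aK + gK) else NA_real_,
            stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(transcript = character(), pos = integer(),
                          strand = character(), aControl = integer(),
                          gControl = integer(), aKD = integer(),
                          gKD = integer(), levelControl = numeric(),
                          levelKD = numeric()))
    do.call(rbind, out)
}

#' Call differential editing sites (DES)
#'
#' One-sided test of whether the editing level G/(A+G) is lower in KD than
#' in control, on the pooled 2x2 count table per site (Fisher exact by
#' default, two-proportion z-test by flag).  A site is a DES when p <
#' \code{alpha} with the lower-in-KD direction; sites significantly
#' \emph{higher} in KD are flagged separately (putative ADAR2 targets).
#' Benjamini-Hochberg q-values over the tested sites are reported.
#'
#' @param sites data.frame from \code{\link{callEditing}}.
#' @param alpha significance level (default 0.05).
#' @param fdrQ q-value threshold reported as \code{passesFdr} (default 0.1).
#' @param test \code{"fisher"} (default) or \code{"ztest"}.
#' @return the input with columns p, q, direction, isDES, higherInKD,
#'   passesFdr added (sites lacking coverage in a condition are dropped).
#' @export
callDES <- function(sites, alpha = 0.05, fdrQ = 0.1,
                    test = c("fisher", "ztest")) {
    test <- match.arg(test)
    covered <- (sites$aControl + sites$gControl) > 0 &
        (sites$aKD + sites$gKD) > 0
    sites <- sites[covered, , drop = FALSE]
    n <- nrow(sites)
    pLower <- pHigher <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        tab <- matrix(c(sites$gControl[i], sites$gKD[i],
                        sites$aControl[i], sites$aKD[i]), nrow = 2L)
        if (test == "fisher") {
            pLower[i] <- fisher.test(tab, alternative = "greater")$p.value
            pHigher[i] <- fisher.test(tab, alternative = "less")$p.value
        } else {
            pr <- stats::prop.test
            nC <- sites$aControl[i] + sites$gControl[i]
            nK <- sites$aKD[i] + sites$gKD[i]
            pLower[i] <- pr(c(sites$gControl[i], sites$gKD[i]), c(nC, nK),
                            alternative = "greater", correct = FALSE)$p.value
            pHigher[i] <- pr(c(sites$gControl[i], sites$gKD[i]), c(nC, nK),
                             alternative = "less", correct = FALSE)$p.value
        }
    }
    sites$p <- pLower
    sites$q <- p.adjust(pLower, "BH")
    sites$direction <- ifelse(sites$levelKD < sites$levelControl,
                              "lower_in_KD", "higher_in_KD")
    sites$isDES <- sites$p < alpha & sites$direction == "lower_in_KD"
    sites$higherInKD <- pHigher < alpha
    sites$passesFdr <- sites$isDES & sites$q < fdrQ
    sites
}

#' Hyper-edited read criteria
#'
#' A read passes when its count of high-quality (Phred >= \code{minQual})
#' A-to-G mismatches is at least \code{lengthFrac} of the read length AND
#' its A-to-G mismatches exceed \code{purity} of all its mismatches.
#'
#' @param reads list of reads; each read is a list with \code{length} and a
#'   data.frame \code{mismatches} with columns \code{ref}, \code{alt},
#'   \code{qual}.
#' @param minQual Phred threshold (default 30).
#' @param lengthFrac minimum A-to-G density (default 0.05 of read length).
#' @param purity minimum A-to-G fraction of all mismatches (default 0.9,
#'   strict).
#' @return data.frame with per-read counts and the pass flag.
#' @export
hyperEditReadFilter <- function(reads, minQual = 30L, lengthFrac = 0.05,
                                purity = 0.9) {
    out <- lapply(seq_along(reads), function(i) {
        rd <- reads[[i]]
        mm <- rd$mismatches
        if (is.null(mm$qual) || any(is.na(mm$qual)))
            stop("read ", i, ": base qualities are required")
        isAG <- mm$ref == "A" & mm$alt == "G"
        nAGhq <- sum(isAG & mm$qual >= minQual)
        nAG <- sum(isAG)
        nOther <- sum(!isAG)
        pass <- nAGhq >= lengthFrac * rd$length &
            nAG > purity * (nAG + nOther)
        data.frame(read = i, length = rd$length, nAGhighQual = nAGhq,
                   nAG = nAG, nOtherMismatch = nOther, pass = pass)
    })
    do.call(rbind, out)
}

#' Pairing context of editing sites within a duplex
#'
#' Classifies each edited adenosine by the base it faces in the duplex
#' register (C = "AC", U/T = "AU", anything else or unpaired = "other") and
#' compares the observed A:C fraction among edited sites with the fraction
#' expected by chance — the A:C share among \emph{all} duplex adenosines
#' facing C or U — by Fisher exact test (edited vs non-edited adenosines).
#'
#' @param sitePos 1-based positions of edited adenosines.
#' @param pairMap integer duplex register (partner index or NA), as in
#'   \linkS4class{SyntheticTranscript}.
#' @param sequence the transcript/duplex RNA or DNA sequence.
#' @return list with per-site \code{class}, \code{observedAC},
#'   \code{expectedAC}, the 2x2 table and Fisher \code{p}.
#' @export
pairContext <- function(sitePos, pairMap, sequence) {
    seq <- .charVec(.toRNA(sequence))
    if (any(seq[sitePos] != "A"))
        stop("site(s) not an adenosine in the reference: ",
             paste(sitePos[seq[sitePos] != "A"], collapse = ", "))
    classify <- function(pos) {
        partner <- pairMap[pos]
        ifelse(is.na(partner), "other",
               ifelse(seq[partner] == "C", "AC",
                      ifelse(seq[partner] == "U", "AU", "other")))
    }
    cls <- vapply(sitePos, classify, "")
    allA <- which(seq == "A" & !is.na(pairMap))
    allCls <- vapply(allA, classify, "")
    edited <- allA %in% sitePos
    obsAC <- sum(cls == "AC"); obsAU <- sum(cls == "AU")
    bgAC <- sum(allCls == "AC" & !edited)
    bgAU <- sum(allCls == "AU" & !edited)
    if (obsAC + obsAU == 0)
        stop("no informative (A:C / A:U) edited adenosines")
    tab <- matrix(c(obsAC, bgAC, obsAU, bgAU), nrow = 2L,
                  dimnames = list(c("edited", "background"), c("AC", "AU")))
    list(class = cls,
         observedAC = obsAC / (obsAC + obsAU),
         expectedAC = sum(allCls == "AC") /
             sum(allCls %in% c("AC", "AU")),
         table = tab,
         p = if (bgAC + bgAU > 0) fisher.test(tab)$p.value else NA_real_)
}

#' Editing level by pairing context
#'
#' Restricts to sites with pooled control coverage A+G strictly above
#' \code{minCov}, summarizes the control editing level per class
#' (min/quartiles/mean/max/sd/N) and contrasts the A:C and A:U level
#' distributions with a two-sided rank-sum test.
#'
#' @param sites data.frame with columns \code{level} (control editing
#'   level), \code{coverage} (pooled A+G), \code{class} ("AC"/"AU"/other).
#' @param minCov coverage threshold (default 5, strict).
#' @return list with a per-class summary data.frame and the Wilcoxon p.
#' @export
levelByContext <- function(sites, minCov = 5L) {
    keep <- sites$coverage > minCov & sites$class %in% c("AC", "AU")
    s <- sites[keep, , drop = FALSE]
    for (cl in c("AC", "AU"))
        if (!sum(s$class == cl))
            stop("no sites in class ", cl, " after coverage filter")
    summarise <- function(v)
        data.frame(min = min(v), q25 = unname(quantile(v, 0.25)),
                   median = stats::median(v), mean = mean(v),
                   q75 = unname(quantile(v, 0.75)), max = max(v),
                   sd = stats::sd(v), n = length(v))
    tab <- do.call(rbind, lapply(c("AC", "AU"), function(cl)
        cbind(class = cl, summarise(s$level[s$class == cl]))))
    p <- wilcox.test(s$level[s$class == "AC"], s$level[s$class == "AU"],
                     exact = FALSE)$p.value
    list(summary = tab, p = p)
}

#' Rank correlation between structure and editing level
#'
#' Spearman correlation between per-transcript DS/(DS+SS) ratios and mean
#' editing levels.
#'
#' @param dsRatios,editingLevels named numeric vectors over matching
#'   transcripts (>= 10 required).
#' @return list with \code{rho} and \code{p}.
#' @export
editingStructureCorrelation <- function(dsRatios, editingLevels) {
    common <- intersect(names(dsRatios), names(editingLevels))
    x <- dsRatios[common]; y <- editingLevels[common]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 10L) stop("need >= 10 transcripts with both quantities")
    if (var(x) == 0 || var(y) == 0)
        stop("constant vector: rank correlation undefined")
    ct <- cor.test(x, y, method = "spearman", exact = FALSE)
    list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
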