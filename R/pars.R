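# PARS scores and per-base structural summaries.

#' Per-base PARS score
#'
#' \code{score[j] = log2((v1[j] + pseudocount) / (s1[j] + pseudocount))}:
#' positive where the double-strand-specific nuclease (V1) cleaves more,
#' negative where the single-strand-specific nuclease (S1) does.
#'
#' @param v1,s1 normalized per-base read-start vectors of one transcript.
#' @param pseudocount added to both counts; with \code{pseudocount = 0} a
#'   zero count makes the score undefined and is an error (use NA-tolerant
#'   \code{pseudocount = 0} only on strictly positive tracks).
#' @return numeric vector of per-base scores.
#' @export
parsScore <- function(v1, s1, pseudocount = 1.0) {
    if (length(v1) != length(s1)) stop("track lengths differ")
    if (pseudocount <= 0 && any(v1 == 0 | s1 == 0))
        stop("pseudocount <= 0 with zero counts makes the score undefined")
    log2((v1 + pseudocount) / (s1 + pseudocount))
}

#' Replicate-averaged PARS profile of one transcript
#'
#' Computes the PARS score per replicate and averages the per-replicate
#' scores (not the counts) for the requested condition.
#'
#' @param x a normalized \linkS4class{ParsExperiment}.
#' @param transcript transcript id.
#' @param condition \code{"control"} or \code{"KD"}.
#' @param pseudocount see \code{\link{parsScore}}.
#' @return numeric vector of per-base mean scores.
#' @export
parsProfile <- function(x, transcript, condition = "control",
                        pseudocount = 1.0) {
    cd <- colData(x)
    reps <- sort(unique(cd$replicate[cd$condition == condition]))
    scores <- vapply(reps, function(r)
        parsScore(getTrack(x, transcript, condition, "V1", r),
                  getTrack(x, transcript, condition, "S1", r),
                  pseudocount),
        numeric(transcriptLengths(x)[[transcript]]))
    rowMeans(as.matrix(scores))
}

#' Region-normalized (relative) profiles and relative PARS score
#'
#' Each track is rescaled to sum to one over the region; the relative PARS
#' score is the log2 ratio of the mean relative V1 and S1 profiles.
#'
#' @param tracks named list of per-base count vectors over the same region;
#'   names must identify the enzyme (contain "V1" or "S1") when the relative
#'   PARS score is wanted.
#' @param pseudocount pseudocount applied on the relative scale for the PARS
#'   ratio (default 0; relative profiles themselves never need one).
#' @return list with \code{profiles} (each summing to 1) and, when both
#'   enzymes are present, \code{relativePars}.
#' @export
relativeProfile <- function(tracks, pseudocount = 0) {
    totals <- vapply(tracks, sum, 0)
    if (any(totals == 0))
        stop("zero region total in sample(s): ",
             paste(names(tracks)[totals == 0], collapse = ", "))
    profiles <- lapply(tracks, function(v) v / sum(v))
    out <- list(profiles = profiles)
    isV1 <- grepl("V1", names(tracks))
    isS1 <- grepl("S1", names(tracks))
    if (any(isV1) && any(isS1)) {
        mV1 <- rowMeans(do.call(cbind, profiles[isV1]))
        mS1 <- rowMeans(do.call(cbind, profiles[isS1]))
        out$relativePars <- log2((mV1 + pseudocount) / (mS1 + pseudocount))
    }
    out
}

#' Agreement of read starts with a known structure
#'
#' The fraction of structure-informative read starts consistent with a
#' reference annotation: V1 starts on known double-stranded (DS) bases plus
#' S1 starts on known single-stranded (SS) bases, over all V1+S1 starts on
#' annotated bases.  Unannotated bases are excluded.
#'
#' @param v1,s1 per-base read-start vectors.
#' @param ann character vector per base: "DS", "SS" or "unknown".
#' @return fraction in [0, 1].
#' @export
agreementWithKnown <- function(v1, s1, ann) {
    ds <- ann == "DS"; ss <- ann == "SS"
    if (!any(ds) || !any(ss))
        stop("annotation must contain at least one DS and one SS base")
    good <- sum(v1[ds]) + sum(s1[ss])
    tot <- sum(v1[ds | ss]) + sum(s1[ds | ss])
    if (tot == 0) stop("no read starts on annotated bases")
    good / tot
}

#' Folding constraints from a PARS profile
#'
#' Bases with score above \code{hi} are constrained paired ('|'), below
#' \code{lo} forced single-stranded ('x'), otherwise free ('.').  When a
#' sequence and differential-editing sites are supplied, sites covered by
#' more than \code{minDesCoverage} reads with mean control editing level
#' above \code{minDesLevel} are substituted A-to-G in the emitted sequence
#' (inosine pairs like G).
#'
#' @param scores per-base PARS scores.
#' @param hi,lo thresholds (defaults 2.5 / -2.5, \code{hi > lo}).
#' @param sequence optional RNA/DNA sequence of the region.
#' @param desSites optional data.frame with columns \code{pos} (1-based in
#'   the region), \code{coverage}, \code{meanControlLevel}.
#' @param minDesCoverage,minDesLevel substitution thresholds (100 reads,
#'   level 0.1).
#' @return list with \code{constraint} (character string) and, when a
#'   sequence was given, \code{sequence} with substitutions applied.
#' @export
constraintsFromPars <- function(scores, hi = 2.5, lo = -2.5, sequence = NULL,
                                desSites = NULL, minDesCoverage = 100,
                                minDesLevel = 0.1) {
    if (hi <= lo) stop("hi must exceed lo")
    sym <- rep(".", length(scores))
    sym[scores > hi] <- "|"
    sym[scores < lo] <- "x"
    out <- list(constraint = paste(sym, collapse = ""))
    if (!is.null(sequence)) {
        s <- .charVec(.toRNA(sequence))
        if (!is.null(desSites) && nrow(desSites)) {
            sub <- desSites$coverage > minDesCoverage &
                desSites$meanControlLevel > minDesLevel
            p <- desSites$pos[sub]
            p <- p[s[p] == "A"]
            s[p] <- "G"
        }
        out$sequence <- paste(s, collapse = "")
    }
    out
}

#' Write a sequence + constraint file for folding tools
#'
#' @param sequence region sequence.
#' @param constraint constraint string from \code{\link{constraintsFromPars}}.
#' @param path output file.
#' @param name FASTA-style header (default "region").
#' @return invisibly, \code{path}.
#' @export
writeConstraintFile <- function(sequence, constraint, path, name = "region") {
    writeLines(c(paste0(">", name), sequence, constraint), path)
    invisible(path)
}

#' Metagene profile around anchor positions
#'
#' Positionwise mean of per-base values over transcripts at offsets
#' \code{-span..span} from each transcript's anchor (e.g. translation
#' start/stop).  Transcripts contribute only offsets that fall inside them.
#'
#' @param values named list of per-base numeric vectors (one per transcript).
#' @param anchors named integer vector of 1-based anchor positions.
#' @param span window half-width in bases (default 150).
#' @return data.frame with columns \code{offset}, \code{mean}, \code{n}.
#' @export
metageneProfile <- function(values, anchors, span = 150L) {
    offs <- -span:span
    acc <- numeric(length(offs)); n <- integer(length(offs))
    for (id in names(values)) {
        v <- values[[id]]
        a <- anchors[[id]]
        if (is.null(a) || is.na(a)) next
        if (a < 1L || a > length(v)) stop("anchor outside transcript ", id)
        p <- a + offs
        ok <- p >= 1L & p <= length(v)
        acc[ok] <- acc[ok] + v[p[ok]]
        n[ok] <- n[ok] + 1L
    }
    data.frame(offset = offs, mean = ifelse(n > 0, acc / pmax(n, 1L), NA),
               n = n)
}

#' Mean score at each codon position of a CDS
#'
#' @param scores per-base scores of the transcript.
#' @param cdsStart,cdsEnd 1-based CDS bounds; a length not divisible by 3 is
#'   truncated (with a message).
#' @return numeric vector of three means (codon positions 1, 2, 3).
#' @export
codonPeriodicity <- function(scores, cdsStart, cdsEnd) {
    len <- cdsEnd - cdsStart + 1L
    if (len < 3L) stop("CDS shorter than one codon")
    if (len %% 3L != 0L) {
        message("CDS length not divisible by 3; truncating ", len %% 3L,
                " trailing base(s)")
        cdsEnd <- cdsStart + (len %/% 3L) * 3L - 1L
    }
    v <- scores[cdsStart:cdsEnd]
    phase <- rep(1:3, length.out = length(v))
    vapply(1:3, function(k) mean(v[phase == k]), 0)
}

#' Fraction of buried bases
#'
#' A base is buried when its normalized count is at most \code{frac} of the
#' transcript's per-base mean in \emph{both} the V1 and the S1 track: low
#' digestion by both enzymes marks solvent-inaccessible bases.
#'
#' @param v1,s1 normalized per-base count vectors.
#' @param frac threshold as a fraction of each enzyme's per-base mean
#'   (default 0.5).
#' @return fraction of buried bases in [0, 1].
#' @export
buriedFraction <- function(v1, s1, frac = 0.5) {
    if (length(v1) != length(s1)) stop("track lengths differ")
    if (length(v1) == 0L) stop("zero-length transcript")
    buried <- v1 <= frac * mean(v1) & s1 <= frac * mean(s1)
    mean(buried)
}
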