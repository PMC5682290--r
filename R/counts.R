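#' @importFrom Rsamtools asBam ScanBamParam scanBamFlag
#' @importFrom GenomicAlignments readGAlignments cigar
#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom IRanges IRanges
NULL

# ---- alignment -> read-start tracks ---------------------------------------

.parseCigar <- function(cig) {
    lens <- as.integer(regmatches(cig, gregexpr("[0-9]+", cig))[[1]])
    ops <- regmatches(cig, gregexpr("[MIDNSHP=X]", cig))[[1]]
    list(ops = ops, lens = lens)
}

# TRUE when the 5' end of the read is aligned to the reference by at least
# minAnchor bases without gaps.  For a plus-strand read the 5' end is the
# leftmost aligned base, so the leading aligned run (after any clip) must be
# a match run of >= minAnchor; mirrored for minus-strand reads.
.anchorOK <- function(cig, negStrand, minAnchor) {
    p <- .parseCigar(cig)
    if (negStrand) { p$ops <- rev(p$ops); p$lens <- rev(p$lens) }
    i <- 1L
    while (i <= length(p$ops) && p$ops[i] %in% c("S", "H")) i <- i + 1L
    i <= length(p$ops) && p$ops[i] %in% c("M", "=", "X") &&
        p$lens[i] >= minAnchor
}

#' Count read starts per base from strand-specific alignments
#'
#' Counts, for one PARS-seq sample, the number of uniquely aligned reads
#' whose 5' end matches the reference by at least \code{minAnchor} bases
#' without gaps, incrementing the count at the 5'-most aligned base.  The
#' protocol is strand specific: reads antisense to their transcript are not
#' counted.  Alignments are expected in transcript space (reference names =
#' transcript ids, all transcripts plus strand).
#'
#' @param file path to a SAM or BAM file.
#' @param models transcript models: a named integer vector of transcript
#'   lengths, or a BED12 file path.
#' @param condition,enzyme,replicate sample metadata.
#' @param minAnchor minimum gap-free 5' match length (default 5).
#' @param minMapq mapping-quality threshold defining "uniquely aligned"
#'   (default 10); when MAPQ is unavailable (255/NA) the secondary-alignment
#'   flag is used instead.
#' @return A one-sample \linkS4class{ParsExperiment}; the numbers of reads
#'   skipped for each reason are recorded in \code{metadata()$skipped}.
#' @export
countReadStarts <- function(file, models, condition, enzyme, replicate = 1L,
                            minAnchor = 5L, minMapq = 10L) {
    if (is.character(models) && length(models) == 1L && file.exists(models))
        models <- .bed12Lengths(models)
    if (is.null(names(models)))
        stop("models must be named transcript lengths or a BED12 file")
    if (grepl("\\.sam$", file, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        file <- asBam(file, destination = dest, overwrite = TRUE,
                      indexDestination = FALSE)
    }
    param <- ScanBamParam(what = c("mapq", "flag"),
                          flag = scanBamFlag(isUnmappedQuery = FALSE))
    aln <- readGAlignments(file, param = param)
    mcols <- S4Vectors::mcols(aln)
    mapq <- mcols$mapq
    unique_ok <- ifelse(!is.na(mapq) & mapq != 255L, mapq >= minMapq,
                        bitwAnd(mcols$flag, 256L) == 0L)
    neg <- as.character(strand(aln)) == "-"
    known <- as.character(seqnames(aln)) %in% names(models)
    anchor_ok <- vapply(seq_along(aln), function(i)
        .anchorOK(cigar(aln)[i], neg[i], minAnchor), TRUE)
    keep <- unique_ok & !neg & known & anchor_ok
    skipped <- c(not_unique = sum(!unique_ok),
                 antisense = sum(neg),
                 unknown_transcript = sum(!known),
                 short_anchor = sum(known & !neg & unique_ok & !anchor_ok))
    fivep <- ifelse(neg, end(aln), start(aln))[keep]
    tx <- as.character(seqnames(aln))[keep]
    lens <- models
    counts <- matrix(0L, nrow = sum(lens), ncol = 1L)
    offsets <- c(0L, cumsum(lens))
    names(offsets) <- c(names(lens), "")
    idx <- offsets[tx] + fivep
    inside <- fivep >= 1L & fivep <= lens[tx]
    tabulated <- tabulate(idx[inside], nbins = sum(lens))
    counts[, 1L] <- tabulated
    pe <- ParsExperiment(counts,
                         transcript = rep(names(lens), lens),
                         pos = unlist(lapply(lens, seq_len), use.names = FALSE),
                         condition = condition, enzyme = enzyme,
                         replicate = replicate)
    metadata(pe)$skipped <- skipped
    pe
}

.bed12Lengths <- function(path) {
    bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    lens <- as.integer(bed[[3]] - bed[[2]])
    names(lens) <- as.character(bed[[4]])
    lens
}

#' Combine single-sample ParsExperiments into one experiment
#'
#' @param ... one-or-more \linkS4class{ParsExperiment} objects over identical
#'   transcripts.
#' @return a combined \linkS4class{ParsExperiment}.
#' @export
combineTracks <- function(...) {
    pes <- list(...)
    if (length(pes) == 1L && is.list(pes[[1]]) && !is(pes[[1]], "ParsExperiment"))
        pes <- pes[[1]]
    ref <- rowData(pes[[1]])
    for (pe in pes[-1])
        if (!identical(as.data.frame(rowData(pe)), as.data.frame(ref)))
            stop("tracks cover different transcripts/bases")
    counts <- do.call(cbind, lapply(pes, function(pe) assay(pe, "counts")))
    cd <- do.call(rbind, lapply(pes, function(pe) as.data.frame(colData(pe))))
    ParsExperiment(counts, transcript = ref$transcript, pos = ref$pos,
                   condition = cd$condition, enzyme = cd$enzyme,
                   replicate = cd$replicate)
}

# ---- track-file I/O -------------------------------------------------------

#' Read tab-delimited read-start tracks into a ParsExperiment
#'
#' Each track file has columns transcript, 0-based position, count; sample
#' metadata (condition, enzyme, replicate) is read from the JSON sidecar
#' \code{<file stem>.json}.
#'
#' @param files character vector of \code{*.track.tsv} paths, or a directory
#'   containing them.
#' @return a \linkS4class{ParsExperiment} of raw counts.
#' @export
readTracks <- function(files) {
    if (length(files) == 1L && dir.exists(files))
        files <- list.files(files, pattern = "\\.track\\.tsv$",
                            full.names = TRUE)
    if (!length(files)) stop("no track files found")
    pes <- lapply(files, function(f) {
        meta <- jsonlite::read_json(sub("\\.tsv$", ".json", f))
        df <- utils::read.table(f, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
        ParsExperiment(matrix(df$count, ncol = 1L),
                       transcript = df$transcript, pos = df$pos + 1L,
                       condition = meta$condition, enzyme = meta$enzyme,
                       replicate = meta$replicate)
    })
    combineTracks(pes)
}

#' Export one sample track as bedGraph (0-based half-open)
#'
#' @param x a \linkS4class{ParsExperiment}.
#' @param sample column index or name.
#' @param path output file.
#' @param assay assay to export.
#' @return invisibly, \code{path}.
#' @export
exportBedGraph <- function(x, sample, path, assay = .defaultAssay(x)) {
    v <- SummarizedExperiment::assay(x, assay)[, sample]
    rd <- rowData(x)
    runs <- S4Vectors::Rle(paste(rd$transcript, v))
    i <- 1L
    lines <- character(S4Vectors::nrun(runs))
    starts <- cumsum(c(0L, S4Vectors::runLength(runs)))
    for (k in seq_len(S4Vectors::nrun(runs))) {
        a <- starts[k] + 1L; b <- starts[k + 1L]
        lines[k] <- paste(rd$transcript[a], rd$pos[a] - 1L, rd$pos[b], v[a],
                          sep = "\t")
    }
    writeLines(lines, path)
    invisible(path)
}

# ---- normalization and expression -----------------------------------------

#' Equalize total read starts across samples
#'
#' Scales every sample by a single factor so that all totals equal the mean
#' of the raw totals (within-track proportions are preserved).  Adds a
#' \code{"normcounts"} assay and a \code{sizeFactor} colData column.
#'
#' @param x a \linkS4class{ParsExperiment}.
#' @return the updated \linkS4class{ParsExperiment}.
#' @export
normalizeTracks <- function(x) {
    counts <- assay(x, "counts")
    totals <- colSums(counts)
    if (any(totals == 0))
        stop("sample(s) with zero total read starts: ",
             paste(colnames(counts)[totals == 0], collapse = ", "))
    target <- mean(totals)
    sf <- target / totals
    assay(x, "normcounts") <- sweep(counts, 2L, sf, `*`)
    colData(x)$sizeFactor <- sf
    x
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' \code{rpkm = 1e9 * count / (length * libraryTotal)}.
#'
#' @param count gene read count(s).
#' @param length transcript length(s) in bases (> 0).
#' @param libraryTotal total mapped reads in the library (> 0).
#' @return numeric RPKM value(s).
#' @export
rpkm <- function(count, length, libraryTotal) {
    if (any(length <= 0)) stop("transcript length must be positive")
    if (any(libraryTotal <= 0)) stop("library total must be positive")
    1e9 * count / (as.numeric(length) * as.numeric(libraryTotal))
}

#' Mean-coverage region filter
#'
#' TRUE when the mean, over all samples, of the total read starts within the
#' region reaches the threshold.  Thresholds of 50/200/1000 reproduce the
#' expression tiers used for region-set enrichment.
#'
#' @param x a \linkS4class{ParsExperiment} (raw counts are used).
#' @param transcript transcript id.
#' @param region integer c(start, end), 1-based inclusive; NULL = whole
#'   transcript.
#' @param minMeanReadStarts threshold.
#' @return logical scalar.
#' @export
meanCoverageFilter <- function(x, transcript, region = NULL,
                               minMeanReadStarts) {
    m <- trackMatrix(x, transcript, assay = "counts")
    if (is.null(region)) region <- c(1L, nrow(m))
    if (region[2] < region[1]) stop("empty region")
    sums <- colSums(m[region[1]:region[2], , drop = FALSE])
    mean(sums) >= minMeanReadStarts
}

# ---- genome-space projection ----------------------------------------------

#' Project genomic point positions into transcript coordinates
#'
#' Maps 1-based genomic positions through a spliced transcript model
#' (exons as a \linkS4class{GRanges}, plus or minus strand) onto 1-based
#' transcript positions.  Positions outside the exons map to NA.
#'
#' @param pos integer vector of genomic positions.
#' @param exons \linkS4class{GRanges} of the transcript's exons.
#' @return integer vector of transcript positions (NA where unmapped).
#' @export
projectToTranscript <- function(pos, exons) {
    exons <- GenomicRanges::sort(exons)
    minus <- as.character(strand(exons)[1]) == "-"
    widths <- end(exons) - start(exons) + 1L
    offs <- cumsum(c(0L, widths[-length(widths)]))
    out <- rep(NA_integer_, length(pos))
    for (i in seq_along(exons)) {
        hit <- pos >= start(exons)[i] & pos <= end(exons)[i]
        out[hit] <- offs[i] + (pos[hit] - start(exons)[i] + 1L)
    }
    if (minus) out <- sum(widths) - out + 1L
    out
}
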