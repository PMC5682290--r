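#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- assayNames rowData colData colData<-
NULL

#' ParsExperiment: per-base read-start tracks for a PARS-seq experiment
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding nuclease
#' read-start counts at single-base resolution.  Rows are transcript bases
#' (rowData columns \code{transcript} and \code{pos}, 1-based transcript
#' coordinates), columns are samples (colData columns \code{condition} in
#' \code{{"control","KD"}}, \code{enzyme} in \code{{"V1","S1"}} and
#' \code{replicate}).  The \code{"counts"} assay stores raw read starts;
#' \code{\link{normalizeTracks}} adds a \code{"normcounts"} assay in which all
#' sample totals are equal.
#'
#' @name ParsExperiment-class
#' @aliases ParsExperiment
#' @exportClass ParsExperiment
setClass("ParsExperiment", contains = "SummarizedExperiment")

.validParsExperiment <- function(object) {
    msg <- character()
    rd <- rowData(object)
    cd <- colData(object)
    if (!all(c("transcript", "pos") %in% colnames(rd)))
        msg <- c(msg, "rowData must have 'transcript' and 'pos' columns")
    if (!all(c("condition", "enzyme", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must have 'condition', 'enzyme', 'replicate'")
    else {
        if (!all(cd$condition %in% c("control", "KD")))
            msg <- c(msg, "condition must be 'control' or 'KD'")
        if (!all(cd$enzyme %in% c("V1", "S1")))
            msg <- c(msg, "enzyme must be 'V1' or 'S1'")
        if (any(cd$replicate < 1))
            msg <- c(msg, "replicate must be >= 1")
    }
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else if (any(assay(object, "counts") < 0))
        msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
}
setValidity("ParsExperiment", .validParsExperiment)

#' Construct a ParsExperiment from a base-by-sample count matrix
#'
#' @param counts numeric matrix, rows = transcript bases, cols = samples.
#' @param transcript character vector, one transcript id per row.
#' @param pos integer vector of 1-based positions within each transcript.
#' @param condition,enzyme,replicate per-sample metadata vectors.
#' @param sampleNames optional column names; defaults to
#'   \code{condition_enzyme_rep<replicate>}.
#' @return A \linkS4class{ParsExperiment}.
#' @export
ParsExperiment <- function(counts, transcript, pos,
                           condition, enzyme, replicate,
                           sampleNames = NULL) {
    counts <- as.matrix(counts)
    if (is.null(sampleNames))
        sampleNames <- paste0(condition, "_", enzyme, "_rep", replicate)
    colnames(counts) <- sampleNames
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(transcript = as.character(transcript),
                            pos = as.integer(pos)),
        colData = DataFrame(condition = condition, enzyme = enzyme,
                            replicate = as.integer(replicate),
                            row.names = sampleNames))
    new("ParsExperiment", se)
}

#' @describeIn ParsExperiment-class compact display
#' @param object a ParsExperiment
#' @export
setMethod("show", "ParsExperiment", function(object) {
    cd <- colData(object)
    cat("ParsExperiment:", length(unique(rowData(object)$transcript)),
        "transcripts,", nrow(object), "bases,", ncol(object), "samples\n")
    cat("  conditions:", paste(unique(cd$condition), collapse = ", "),
        "| enzymes:", paste(unique(cd$enzyme), collapse = ", "),
        "| replicates:", paste(sort(unique(cd$replicate)), collapse = ","),
        "\n")
    cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
})

#' Transcript ids present in a ParsExperiment
#' @param x a ParsExperiment
#' @return character vector of transcript identifiers (in row order).
#' @export
transcriptIds <- function(x) unique(rowData(x)$transcript)

#' Transcript lengths (number of bases) in a ParsExperiment
#' @param x a ParsExperiment
#' @return named integer vector.
#' @export
transcriptLengths <- function(x) {
    tab <- table(rowData(x)$transcript)
    out <- as.integer(tab)
    names(out) <- names(tab)
    out[transcriptIds(x)]
}

.defaultAssay <- function(x) {
    if ("normcounts" %in% assayNames(x)) "normcounts" else "counts"
}

#' Extract the base-by-sample track matrix of one transcript
#'
#' @param x a ParsExperiment
#' @param transcript transcript id.
#' @param assay assay name; defaults to \code{"normcounts"} when present.
#' @return numeric matrix (bases x samples), rows ordered by position.
#' @export
trackMatrix <- function(x, transcript, assay = .defaultAssay(x)) {
    keep <- rowData(x)$transcript == transcript
    if (!any(keep)) stop("unknown transcript: ", transcript)
    m <- SummarizedExperiment::assay(x, assay)[keep, , drop = FALSE]
    m[order(rowData(x)$pos[keep]), , drop = FALSE]
}

#' Extract a single per-base track
#'
#' @inheritParams trackMatrix
#' @param condition,enzyme,replicate sample selectors.
#' @return numeric vector of per-base read starts.
#' @export
getTrack <- function(x, transcript, condition, enzyme, replicate = 1L,
                     assay = .defaultAssay(x)) {
    cd <- colData(x)
    j <- which(cd$condition == condition & cd$enzyme == enzyme &
               cd$replicate == replicate)
    if (length(j) != 1L)
        stop("no unique sample for ", condition, "/", enzyme,
             "/rep", replicate)
    trackMatrix(x, transcript, assay)[, j]
}

#' Synthetic transcript with a 3'UTR inverted-repeat duplex
#'
#' Ground-truth object produced by \code{\link{makeTranscriptome}}.  The
#' \code{pairMap} slot records the duplex register: for every base inside an
#' inverted-repeat arm, the index of the base it faces on the opposite arm
#' (NA outside the duplex).  Whether a faced base pair is actually paired
#' depends on base identity and editing state (A:U and I:C pair; A:C and I:U
#' do not) and is computed by \code{\link{basePairedState}} and
#' \code{\link{realizeMolecules}}.
#'
#' @slot id transcript identifier.
#' @slot seq RNA sequence (A/C/G/U).
#' @slot pairMap integer vector, duplex register partner index or NA.
#' @slot editSites data.frame with columns \code{pos}, \code{partner},
#'   \code{context} ("AC"/"AU"), \code{levelControl}, \code{levelKD}.
#' @slot regionLabels per-base annotation: "5UTR", "CDS", "3UTR" or "IR_arm".
#' @exportClass SyntheticTranscript
setClass("SyntheticTranscript",
    representation(id = "character", seq = "character",
                   pairMap = "integer", editSites = "data.frame",
                   regionLabels = "character"))

.validSyntheticTranscript <- function(object) {
    msg <- character()
    L <- nchar(object@seq)
    pm <- object@pairMap
    if (length(pm) != L) msg <- c(msg, "pairMap length != sequence length")
    idx <- which(!is.na(pm))
    if (length(idx) && !identical(pm[pm[idx]], idx))
        msg <- c(msg, "pairMap is not symmetric")
    es <- object@editSites
    if (nrow(es)) {
        b <- substring(object@seq, es$pos, es$pos)
        if (!all(b == "A")) msg <- c(msg, "edit sites must fall on A bases")
        lv <- c(es$levelControl, es$levelKD)
        if (any(lv < 0 | lv > 1)) msg <- c(msg, "editing levels must be in [0,1]")
        if (any(es$levelKD > es$levelControl + 1e-12))
            msg <- c(msg, "KD level must not exceed control level")
    }
    if (length(object@regionLabels) != L)
        msg <- c(msg, "regionLabels length != sequence length")
    if (length(msg)) msg else TRUE
}
setValidity("SyntheticTranscript", .validSyntheticTranscript)

#' @describeIn SyntheticTranscript-class compact display
#' @param object a SyntheticTranscript
#' @export
setMethod("show", "SyntheticTranscript", function(object) {
    cat("SyntheticTranscript", object@id, ":", nchar(object@seq), "nt,",
        sum(!is.na(object@pairMap)), "duplex bases,",
        nrow(object@editSites), "edit sites\n")
})

#' Configuration for the synthetic PARS-seq experiment generator
#'
#' All randomness in the generator is fixed by \code{seed}.  The nuclease
#' rates are relative per-base cleavage propensities: V1 prefers paired (DS)
#' bases, S1 prefers unpaired (SS) bases.
#'
#' @slot nTranscripts number of transcripts.
#' @slot lengthRange integer range of transcript lengths (bases).
#' @slot armLength inverted-repeat arm length (bases).
#' @slot armGap loop length separating the two arms (bases).
#' @slot armMismatchRate per-base probability that an arm position is a
#'   mismatch in the duplex (imperfect inverted repeats).
#' @slot acFraction fraction of planted mismatches made A:C.
#' @slot fracSWE,fracDSWE fractions of transcripts carrying A:C-site editing
#'   (stabilised while edited) and A:U-site editing (destabilised while
#'   edited); the remainder are unedited.
#' @slot editSitesPerTranscript editing sites seeded per edited transcript.
#' @slot editLevelMeanAC,editLevelMeanAU,editLevelSd Beta-distribution
#'   moments of true control editing levels by pairing context.
#' @slot kdRetention KD editing level as a fraction of the control level.
#' @slot readDepth read starts per transcript per sample.
#' @slot nMolecules molecules realised per transcript per replicate.
#' @slot v1DsRate,v1SsRate,s1DsRate,s1SsRate relative cleavage rates.
#' @slot nReplicates biological replicates per condition/enzyme.
#' @slot pileupCoverage per-site A/G coverage per replicate in the simulated
#'   pileups.
#' @slot readLength simulated read length (read-level simulation only).
#' @slot seed integer seed fixing all randomness.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(nTranscripts = "integer", lengthRange = "integer",
        armLength = "integer", armGap = "integer",
        armMismatchRate = "numeric", acFraction = "numeric",
        fracSWE = "numeric", fracDSWE = "numeric",
        editSitesPerTranscript = "integer",
        editLevelMeanAC = "numeric", editLevelMeanAU = "numeric",
        editLevelSd = "numeric", kdRetention = "numeric",
        readDepth = "integer", nMolecules = "integer",
        v1DsRate = "numeric", v1SsRate = "numeric",
        s1DsRate = "numeric", s1SsRate = "numeric",
        nReplicates = "integer", pileupCoverage = "integer",
        readLength = "integer", seed = "integer"))

.validSimulationConfig <- function(object) {
    msg <- character()
    r <- c(object@v1DsRate, object@v1SsRate, object@s1DsRate, object@s1SsRate)
    if (any(r < 0)) msg <- c(msg, "cleavage rates must be >= 0")
    if (object@v1DsRate <= object@v1SsRate)
        msg <- c(msg, "v1DsRate must exceed v1SsRate")
    if (object@s1SsRate <= object@s1DsRate)
        msg <- c(msg, "s1SsRate must exceed s1DsRate")
    if (object@armMismatchRate < 0 || object@armMismatchRate > 1)
        msg <- c(msg, "armMismatchRate must be in [0,1]")
    if (object@acFraction < 0 || object@acFraction > 1)
        msg <- c(msg, "acFraction must be in [0,1]")
    if (object@fracSWE + object@fracDSWE > 1)
        msg <- c(msg, "fracSWE + fracDSWE must be <= 1")
    if (object@kdRetention < 0 || object@kdRetention > 1)
        msg <- c(msg, "kdRetention must be in [0,1]")
    if (diff(object@lengthRange) < 0)
        msg <- c(msg, "lengthRange must be increasing")
    if (object@readDepth <= 0) msg <- c(msg, "readDepth must be positive")
    if (object@nReplicates < 1) msg <- c(msg, "nReplicates must be >= 1")
    if (length(msg)) msg else TRUE
}
setValidity("SimulationConfig", .validSimulationConfig)

#' Create a simulator configuration
#'
#' Defaults encode the emulated study conditions: imperfect inverted-repeat
#' duplexes with ~15\% arm mismatches, a knockdown retaining 30\% of the
#' control editing level, two biological replicates per sample, and 1e4 read
#' starts per transcript.
#'
#' @param nTranscripts,lengthRange,armLength,armGap,armMismatchRate,acFraction
#'   see \linkS4class{SimulationConfig}.
#' @param fracSWE,fracDSWE,editSitesPerTranscript,editLevelMeanAC,editLevelMeanAU,editLevelSd
#'   see \linkS4class{SimulationConfig}.
#' @param kdRetention,readDepth,nMolecules,v1DsRate,v1SsRate,s1DsRate,s1SsRate
#'   see \linkS4class{SimulationConfig}.
#' @param nReplicates,pileupCoverage,readLength,seed
#'   see \linkS4class{SimulationConfig}.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nTranscripts = 100L, lengthRange = c(900L, 1100L),
        armLength = 150L, armGap = 40L, armMismatchRate = 0.15,
        acFraction = 0.5, fracSWE = 0.5, fracDSWE = 0.1,
        editSitesPerTranscript = 24L, editLevelMeanAC = 0.5,
        editLevelMeanAU = 0.35, editLevelSd = 0.10, kdRetention = 0.3,
        readDepth = 10000L, nMolecules = 300L, v1DsRate = 1, v1SsRate = 0.05,
        s1DsRate = 0.05, s1SsRate = 1, nReplicates = 2L,
        pileupCoverage = 100L, readLength = 36L, seed = 1L) {
    new("SimulationConfig",
        nTranscripts = as.integer(nTranscripts),
        lengthRange = as.integer(lengthRange),
        armLength = as.integer(armLength), armGap = as.integer(armGap),
        armMismatchRate = armMismatchRate, acFraction = acFraction,
        fracSWE = fracSWE, fracDSWE = fracDSWE,
        editSitesPerTranscript = as.integer(editSitesPerTranscript),
        editLevelMeanAC = editLevelMeanAC, editLevelMeanAU = editLevelMeanAU,
        editLevelSd = editLevelSd, kdRetention = kdRetention,
        readDepth = as.integer(readDepth), nMolecules = as.integer(nMolecules),
        v1DsRate = v1DsRate, v1SsRate = v1SsRate,
        s1DsRate = s1DsRate, s1SsRate = s1SsRate,
        nReplicates = as.integer(nReplicates),
        pileupCoverage = as.integer(pileupCoverage),
        readLength = as.integer(readLength), seed = as.integer(seed))
}

#' @describeIn SimulationConfig-class compact display
#' @param object a SimulationConfig
#' @export
setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nTranscripts, "transcripts,",
        "arm", object@armLength, "nt @", object@armMismatchRate,
        "mismatch, depth", object@readDepth, "x", object@nReplicates,
        "reps, seed", object@seed, "\n")
})
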