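#' @importFrom stats rbinom rmultinom runif rbeta
NULL

# ---- transcriptome construction -------------------------------------------

# Core generator, consumes the current RNG stream (seeding is handled by the
# exported wrappers so composite simulations stay on one deterministic
# stream).
.makeTranscriptome <- function(config) {
    n <- config@nTranscripts
    classes <- rep("none", n)
    if (n > 0) {
        nSWE <- round(config@fracSWE * n)
        nDSWE <- round(config@fracDSWE * n)
        classes[seq_len(nSWE)] <- "SWE"
        if (nDSWE > 0) classes[nSWE + seq_len(nDSWE)] <- "DSWE"
        classes <- sample(classes)
    }
    transcripts <- vector("list", n)
    for (i in seq_len(n)) {
        transcripts[[i]] <- .makeOneTranscript(
            id = sprintf("tx%04d", i), class = classes[i], config = config)
    }
    txTruth <- data.frame(
        transcript = vapply(transcripts, function(t) t@id, ""),
        length = vapply(transcripts, function(t) nchar(t@seq), 0L),
        class = classes,
        nEditSites = vapply(transcripts, function(t) nrow(t@editSites), 0L),
        stringsAsFactors = FALSE)
    txTruth$trueSSC <- txTruth$nEditSites > 0
    siteTruth <- do.call(rbind, lapply(transcripts, function(t) {
        if (!nrow(t@editSites)) return(NULL)
        cbind(data.frame(transcript = t@id, stringsAsFactors = FALSE),
              t@editSites)
    }))
    if (is.null(siteTruth))
        siteTruth <- data.frame(transcript = character(), pos = integer(),
                                partner = integer(), context = character(),
                                levelControl = numeric(), levelKD = numeric())
    list(transcripts = transcripts,
         truth = list(transcripts = txTruth, sites = siteTruth))
}

.makeOneTranscript <- function(id, class, config) {
    L <- sample(seq(config@lengthRange[1], config@lengthRange[2]), 1L)
    utr5 <- max(1L, floor(0.1 * L))
    cds <- max(3L, (floor(0.4 * L) %/% 3L) * 3L)
    utr3Start <- utr5 + cds + 1L
    K <- config@armLength
    arm1Start <- utr3Start + 10L
    arm2Start <- arm1Start + K + config@armGap
    if (K > L || arm2Start + K - 1L > L - 2L)
        stop("invalid config: duplex arms (length ", K,
             ") do not fit in the 3'UTR of a transcript of length ", L)
    seq <- sample(.RNA_BASES, L, replace = TRUE)
    arm1 <- arm1Start:(arm1Start + K - 1L)
    arm2 <- arm2Start:(arm2Start + K - 1L)
    pairMap <- rep(NA_integer_, L)
    pairMap[arm1] <- rev(arm2)
    pairMap[arm2] <- rev(arm1)
    # start from a perfect duplex, then plant mismatches
    seq[rev(arm2)] <- .charVec(.rnaComplement(paste(seq[arm1], collapse = "")))
    mism <- runif(K) < config@armMismatchRate
    for (i in which(mism)) {
        p <- arm1[i]; q <- pairMap[p]
        if (runif(1) < config@acFraction) {          # planted A:C mismatch
            seq[p] <- "A"; seq[q] <- "C"
        } else {                                     # other mismatch type
            bad <- c(.rnaComplement(seq[p]),
                     if (seq[p] == "A") "C",
                     if (seq[p] == "C") "A")
            seq[q] <- sample(setdiff(.RNA_BASES, bad), 1L)
        }
    }
    labels <- rep("3UTR", L)
    labels[seq_len(utr5)] <- "5UTR"
    labels[(utr5 + 1L):(utr5 + cds)] <- "CDS"
    labels[c(arm1, arm2)] <- "IR_arm"
    # seed editing sites on arm adenosines according to the transcript class
    duplexA <- which(seq == "A" & !is.na(pairMap))
    ctx <- ifelse(seq[pairMap[duplexA]] == "C", "AC",
                  ifelse(seq[pairMap[duplexA]] == "U", "AU", "other"))
    pool <- switch(class,
        SWE = duplexA[ctx == "AC"],
        DSWE = duplexA[ctx == "AU"],
        integer(0))
    nSites <- min(length(pool), config@editSitesPerTranscript)
    sites <- if (nSites > 0)
        sort(pool[sample.int(length(pool), nSites)]) else integer(0)
    sctx <- ifelse(seq[pairMap[sites]] == "C", "AC", "AU")
    lvl <- numeric(nSites)
    lvl[sctx == "AC"] <- .rbetaMS(sum(sctx == "AC"), config@editLevelMeanAC,
                                  config@editLevelSd)
    lvl[sctx == "AU"] <- .rbetaMS(sum(sctx == "AU"), config@editLevelMeanAU,
                                  config@editLevelSd)
    editSites <- data.frame(pos = as.integer(sites),
                            partner = pairMap[sites],
                            context = as.character(sctx),
                            levelControl = lvl,
                            levelKD = config@kdRetention * lvl,
                            stringsAsFactors = FALSE)
    new("SyntheticTranscript", id = id, seq = paste(seq, collapse = ""),
        pairMap = pairMap, editSites = editSites, regionLabels = labels)
}

#' Generate a synthetic transcriptome with known structural truth
#'
#' Each transcript carries an imperfect inverted-repeat duplex in its 3'UTR.
#' A configured fraction of transcripts carries A:C-context editing sites
#' (editing to I:C pairs the bases: stabilised while edited) and a fraction
#' carries A:U-context sites (editing to I:U unpairs them: destabilised
#' while edited).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{transcripts} (list of
#'   \linkS4class{SyntheticTranscript}) and \code{truth} (list with
#'   per-transcript and per-site data.frames).
#' @export
makeTranscriptome <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    .withSeed(config@seed, .makeTranscriptome(config))
}

# ---- molecule-level editing and pairing -----------------------------------

#' Baseline or edited pairing state of each base
#'
#' A duplex-register base is paired when the base it faces is Watson-Crick
#' complementary, with inosine read as G: an edited A:U becomes I:U
#' (unpaired) and an edited A:C becomes I:C (paired).
#'
#' @param t a \linkS4class{SyntheticTranscript}.
#' @param edited logical vector over \code{t@editSites} rows (default all
#'   unedited).
#' @return logical vector over bases; TRUE = paired.
#' @export
basePairedState <- function(t, edited = rep(FALSE, nrow(t@editSites))) {
    seq <- .charVec(t@seq)
    pm <- t@pairMap
    paired <- !is.na(pm)
    idx <- which(paired)
    paired[idx] <- seq[pm[idx]] == .charVec(.rnaComplement(
        paste(seq[idx], collapse = "")))
    es <- t@editSites
    for (k in seq_len(nrow(es))) {
        state <- if (edited[k]) es$context[k] == "AC" else es$context[k] == "AU"
        rows <- c(es$pos[k], es$partner[k])
        paired[rows[!is.na(rows)]] <- state
    }
    paired
}

#' Realize an ensemble of RNA molecules under condition-dependent editing
#'
#' Each molecule edits each site independently with the condition's true
#' editing level; its per-base pairing state is recomputed under the
#' I:C-paired / I:U-unpaired rule.
#'
#' @param t a \linkS4class{SyntheticTranscript}.
#' @param condition \code{"control"} or \code{"KD"}.
#' @param nMolecules number of molecules.
#' @param seed optional integer seed.
#' @return list with \code{id}, \code{condition}, \code{paired}
#'   (bases x molecules logical matrix), \code{edited}
#'   (sites x molecules logical matrix) and \code{sites}.
#' @export
realizeMolecules <- function(t, condition, nMolecules, seed = NULL) {
    if (!condition %in% c("control", "KD"))
        stop("condition must be 'control' or 'KD'")
    .withSeed(seed, {
        es <- t@editSites
        lvl <- if (condition == "control") es$levelControl else es$levelKD
        nS <- nrow(es)
        edited <- matrix(runif(nS * nMolecules) < rep(lvl, nMolecules),
                         nrow = nS)
        base <- basePairedState(t)
        paired <- matrix(base, nrow = length(base), ncol = nMolecules)
        for (k in seq_len(nS)) {
            rows <- c(es$pos[k], es$partner[k])
            rows <- rows[!is.na(rows)]
            paired[rows, ] <- rep(ifelse(edited[k, ], es$context[k] == "AC",
                                         es$context[k] == "AU"),
                                  each = length(rows))
        }
        list(id = t@id, condition = condition, paired = paired,
             edited = edited, sites = es)
    })
}

# per-base cleavage weights for one enzyme, averaged over molecules
.digestWeights <- function(ensemble, enzyme, config) {
    if (!enzyme %in% c("V1", "S1")) stop("enzyme must be 'V1' or 'S1'")
    ds <- if (enzyme == "V1") config@v1DsRate else config@s1DsRate
    ss <- if (enzyme == "V1") config@v1SsRate else config@s1SsRate
    pPaired <- rowMeans(ensemble$paired)
    pPaired * ds + (1 - pPaired) * ss
}

#' Simulate nuclease digestion read starts for one molecule ensemble
#'
#' Read starts are drawn multinomially over bases with per-base weight equal
#' to the enzyme's DS rate where paired and SS rate where unpaired, averaged
#' over the molecules of the ensemble.
#'
#' @param ensemble output of \code{\link{realizeMolecules}}.
#' @param enzyme \code{"V1"} or \code{"S1"}.
#' @param depth total read starts to draw (> 0).
#' @param config a \linkS4class{SimulationConfig} (cleavage rates).
#' @param seed optional integer seed.
#' @return integer vector of per-base read-start counts summing to
#'   \code{depth} (all zero when every weight is zero).
#' @export
simulateDigestion <- function(ensemble, enzyme, depth, config, seed = NULL) {
    if (depth <= 0) stop("depth must be positive")
    w <- .digestWeights(ensemble, enzyme, config)
    .withSeed(seed, {
        if (sum(w) == 0) return(integer(length(w)))
        as.integer(rmultinom(1L, depth, w))
    })
}

#' Simulate covering reads around editing sites of one sample
#'
#' Read-level counterpart of \code{\link{simulateDigestion}} used by the
#' edited-versus-non-edited profile comparison: each read records its start
#' and, when it covers \code{site}, the base observed there (G when the
#' molecule is edited, A otherwise).
#'
#' @param t a \linkS4class{SyntheticTranscript}.
#' @param condition,enzyme sample class.
#' @param site 1-based focal position (an editing site of \code{t}).
#' @param nReads reads to draw.
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed optional integer seed.
#' @return data.frame with columns \code{start} and \code{baseAtSite}
#'   ("A"/"G"/NA when the read does not cover the site).
#' @export
simulateReads <- function(t, condition, enzyme, site, nReads, config,
                          seed = NULL) {
    .withSeed(seed, {
        ens <- realizeMolecules(t, condition, config@nMolecules)
        L <- nchar(t@seq)
        ds <- if (enzyme == "V1") config@v1DsRate else config@s1DsRate
        ss <- if (enzyme == "V1") config@v1SsRate else config@s1SsRate
        k <- match(site, ens$sites$pos)
        mIdx <- sample(config@nMolecules, nReads, replace = TRUE)
        start <- integer(nReads)
        for (m in unique(mIdx)) {
            sel <- mIdx == m
            w <- ifelse(ens$paired[, m], ds, ss)
            if (sum(w) == 0) w <- rep(1, L)
            start[sel] <- sample.int(L, sum(sel), replace = TRUE, prob = w)
        }
        covers <- start <= site & start + config@readLength - 1L >= site
        base <- rep(NA_character_, nReads)
        if (!is.na(k))
            base[covers] <- ifelse(ens$edited[k, mIdx[covers]], "G", "A")
        else base[covers] <- "A"
        data.frame(start = start, baseAtSite = base,
                   stringsAsFactors = FALSE)
    })
}

# ---- full experiment ------------------------------------------------------

#' Simulate a complete PARS-seq experiment with ground truth
#'
#' Generates the transcriptome, realizes molecule ensembles per condition and
#' replicate, digests each with V1 and S1, and assembles the tracks into a
#' \linkS4class{ParsExperiment}.  All randomness is fixed by
#' \code{config@seed}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{experiment} (ParsExperiment),
#'   \code{transcripts}, and \code{truth}.
#' @export
simulateExperiment <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    .withSeed(config@seed, {
        tr <- .makeTranscriptome(config)
        txs <- tr$transcripts
        lens <- vapply(txs, function(t) nchar(t@seq), 0L)
        samples <- expand.grid(replicate = seq_len(config@nReplicates),
                               enzyme = c("V1", "S1"),
                               condition = c("control", "KD"),
                               stringsAsFactors = FALSE)
        counts <- matrix(0L, nrow = sum(lens), ncol = nrow(samples))
        offsets <- c(0L, cumsum(lens))
        for (cond in c("control", "KD")) {
            for (rep in seq_len(config@nReplicates)) {
                for (i in seq_along(txs)) {
                    ens <- realizeMolecules(txs[[i]], cond, config@nMolecules)
                    rows <- (offsets[i] + 1L):offsets[i + 1L]
                    for (enz in c("V1", "S1")) {
                        j <- which(samples$condition == cond &
                                   samples$enzyme == enz &
                                   samples$replicate == rep)
                        counts[rows, j] <- simulateDigestion(
                            ens, enz, config@readDepth, config)
                    }
                }
            }
        }
        pe <- ParsExperiment(
            counts,
            transcript = rep(vapply(txs, function(t) t@id, ""), lens),
            pos = unlist(lapply(lens, seq_len)),
            condition = samples$condition, enzyme = samples$enzyme,
            replicate = samples$replicate)
        list(experiment = pe, transcripts = txs, truth = tr$truth)
    })
}

#' Simulate per-site A/G pileup counts at the editing sites
#'
#' Draws, per condition and replicate, binomial G counts at each editing
#' site from its true level at the configured coverage.
#'
#' @param transcripts list of \linkS4class{SyntheticTranscript}.
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed optional integer seed (defaults to \code{config@seed + 1}).
#' @return data.frame with columns transcript, pos, strand, condition,
#'   replicate, A, C, G, T.
#' @export
simulatePileups <- function(transcripts, config, seed = config@seed + 1L) {
    .withSeed(seed, {
        out <- list()
        for (t in transcripts) {
            es <- t@editSites
            if (!nrow(es)) next
            for (cond in c("control", "KD")) {
                lvl <- if (cond == "control") es$levelControl else es$levelKD
                for (rep in seq_len(config@nReplicates)) {
                    g <- rbinom(nrow(es), config@pileupCoverage, lvl)
                    out[[length(out) + 1L]] <- data.frame(
                        transcript = t@id, pos = es$pos, strand = "+",
                        condition = cond, replicate = rep,
                        A = config@pileupCoverage - g, C = 0L, G = g, T = 0L,
                        stringsAsFactors = FALSE)
                }
            }
        }
        if (!length(out))
            return(data.frame(transcript = character(), pos = integer(),
                              strand = character(), condition = character(),
                              replicate = integer(), A = integer(),
                              C = integer(), G = integer(), T = integer()))
        do.call(rbind, out)
    })
}

#' Simulate A/G pileup counts for explicit true levels
#'
#' Convenience generator for calibration studies: one site per element of
#' \code{levelControl}/\code{levelKD}.
#'
#' @param levelControl,levelKD true editing levels per site.
#' @param coverage A+G coverage per replicate.
#' @param nReplicates replicates per condition.
#' @param seed optional integer seed.
#' @return data.frame in \code{\link{callEditing}} site format with pooled
#'   per-condition A and G counts per replicate.
#' @export
simulateSitePileup <- function(levelControl, levelKD, coverage,
                               nReplicates = 2L, seed = NULL) {
    .withSeed(seed, {
        n <- length(levelControl)
        out <- list()
        for (cond in c("control", "KD")) {
            lvl <- if (cond == "control") levelControl else levelKD
            for (rep in seq_len(nReplicates)) {
                g <- rbinom(n, coverage, lvl)
                out[[length(out) + 1L]] <- data.frame(
                    transcript = sprintf("site%05d", seq_len(n)),
                    pos = seq_len(n), strand = "+", condition = cond,
                    replicate = rep, A = coverage - g, C = 0L, G = g, T = 0L,
                    stringsAsFactors = FALSE)
            }
        }
        do.call(rbind, out)
    })
}

#' Inverted-repeat duplex regions of synthetic transcripts
#'
#' The c(start, end) span of the two IR arms (the natural exon-grain region
#' for structural-change scanning, where the condition-dependent pairing
#' lives).
#'
#' @param transcripts list of \linkS4class{SyntheticTranscript}.
#' @return named list of integer c(start, end).
#' @export
duplexRegions <- function(transcripts) {
    out <- lapply(transcripts, function(t)
        range(which(t@regionLabels == "IR_arm")))
    names(out) <- vapply(transcripts, function(t) t@id, "")
    out
}

# ---- fixture emission -----------------------------------------------------

#' Write simulated data to disk in standard plain-text formats
#'
#' Emits a DNA-alphabet FASTA of the transcript sequences, a BED12 file of
#' the transcript models (0-based half-open, CDS as the thick region), one
#' tab-delimited read-start track per sample (columns transcript, 0-based
#' position, count; sample metadata in a JSON sidecar), per-condition pileup
#' tables, and the ground truth as JSON.
#'
#' @param transcripts list of \linkS4class{SyntheticTranscript}.
#' @param experiment a \linkS4class{ParsExperiment} of raw counts.
#' @param truth truth list from \code{\link{makeTranscriptome}} or
#'   \code{\link{simulateExperiment}}.
#' @param outdir output directory (created if needed).
#' @param pileups optional data.frame from \code{\link{simulatePileups}}.
#' @return invisibly, a character vector of the files written.
#' @export
emitFixtures <- function(transcripts, experiment = NULL, truth = list(),
                         outdir, pileups = NULL) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    written <- character()
    emit <- function(path) { written <<- c(written, path); path }
    ids <- vapply(transcripts, function(t) t@id, "")
    seqs <- Biostrings::DNAStringSet(
        vapply(transcripts, function(t) .toDNA(t@seq), ""))
    names(seqs) <- ids
    Biostrings::writeXStringSet(seqs, emit(file.path(outdir, "sequences.fa")))
    bed <- vapply(transcripts, function(t) {
        L <- nchar(t@seq)
        cds <- range(which(t@regionLabels == "CDS"))
        if (!is.finite(cds[1])) cds <- c(1L, 0L)
        paste(t@id, 0L, L, t@id, 0L, "+", cds[1] - 1L, cds[2], 0L, 1L,
              paste0(L, ","), "0,", sep = "\t")
    }, "")
    writeLines(bed, emit(file.path(outdir, "models.bed")))
    cd <- if (!is.null(experiment)) colData(experiment) else NULL
    rd <- if (!is.null(experiment)) rowData(experiment) else NULL
    for (j in seq_len(if (is.null(experiment)) 0L else ncol(experiment))) {
        stem <- sprintf("%s_%s_rep%d", cd$condition[j], cd$enzyme[j],
                        cd$replicate[j])
        df <- data.frame(transcript = rd$transcript, pos = rd$pos - 1L,
                         count = assay(experiment, "counts")[, j])
        utils::write.table(df, emit(file.path(outdir,
                                              paste0(stem, ".track.tsv"))),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
            list(condition = cd$condition[j], enzyme = cd$enzyme[j],
                 replicate = cd$replicate[j]),
            emit(file.path(outdir, paste0(stem, ".track.json"))),
            auto_unbox = TRUE)
    }
    if (!is.null(pileups)) {
        for (cond in unique(pileups$condition)) {
            for (rep in unique(pileups$replicate)) {
                sel <- pileups$condition == cond & pileups$replicate == rep
                utils::write.table(
                    pileups[sel, c("transcript", "pos", "strand",
                                   "A", "C", "G", "T")],
                    emit(file.path(outdir, sprintf("pileup_%s_rep%d.tsv",
                                                   cond, rep))),
                    sep = "\t", quote = FALSE, row.names = FALSE)
            }
        }
    }
    jsonlite::write_json(truth, emit(file.path(outdir, "truth.json")),
                         dataframe = "columns", digits = NA)
    invisible(written)
}
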