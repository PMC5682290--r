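# Correlation-difference (CorDiff) statistic, permutation null, and SSC
# region calling.

#' @importFrom stats cor var
NULL

#' Correlation difference between structural profiles
#'
#' \code{CorDiff = Cor(c1,c2)^2 + Cor(kd1,kd2)^2 - Cor(c1,kd1)^2 -
#' Cor(c2,kd2)^2} with Pearson correlations: reproducible within-condition
#' profiles that differ across conditions give large positive values;
#' CorDiff is always in [-2, 2].
#'
#' @param c1,c2,kd1,kd2 read-start count vectors over the same region
#'   (length >= 3, each with nonzero variance).
#' @return numeric CorDiff value.
#' @export
corDiff <- function(c1, c2, kd1, kd2) {
    vs <- list(c1 = c1, c2 = c2, kd1 = kd1, kd2 = kd2)
    L <- unique(lengths(vs))
    if (length(L) != 1L || L < 3L)
        stop("vectors must share one length >= 3")
    zv <- vapply(vs, function(v) var(v) == 0, TRUE)
    if (any(zv))
        stop("zero-variance vector(s): ", paste(names(vs)[zv], collapse = ", "),
             " (Pearson correlation undefined; region should be skipped)")
    cor(c1, c2)^2 + cor(kd1, kd2)^2 - cor(c1, kd1)^2 - cor(c2, kd2)^2
}

#' Empirical permutation p-value for an observed CorDiff
#'
#' Each trial independently permutes the positions within every sample's
#' vector and recomputes CorDiff; the p-value is the fraction of trials
#' whose shuffled CorDiff is at least the observed one (ties count against
#' significance).  The observed statistic is significant at 0.05 when it
#' exceeds 95\% of the random trials.
#'
#' @param c1,c2,kd1,kd2 count vectors as in \code{\link{corDiff}}.
#' @param nPerm number of random trials (default 100; fewer than 20 gives a
#'   warning about p-value resolution).
#' @param seed optional integer seed.
#' @param coupled when TRUE all four vectors are shuffled with the same
#'   permutation per trial (off by default).
#' @return list with \code{observed}, \code{p} (raw fraction),
#'   \code{pAdd1} (add-one corrected), and \code{trials}.
#' @export
permutationP <- function(c1, c2, kd1, kd2, nPerm = 100L, seed = NULL,
                         coupled = FALSE) {
    if (nPerm < 20L) warning("nPerm < 20: empirical p has poor resolution")
    obs <- corDiff(c1, c2, kd1, kd2)
    L <- length(c1)
    .withSeed(seed, {
        trials <- vapply(seq_len(nPerm), function(i) {
            if (coupled) {
                o <- sample.int(L)
                corDiff(c1[o], c2[o], kd1[o], kd2[o])
            } else {
                corDiff(c1[sample.int(L)], c2[sample.int(L)],
                        kd1[sample.int(L)], kd2[sample.int(L)])
            }
        }, 0)
        p <- mean(trials >= obs)
        list(observed = obs, p = p, pAdd1 = (sum(trials >= obs) + 1) /
                 (nPerm + 1), trials = trials)
    })
}

#' Scan transcripts (or regions) for secondary-structure changes
#'
#' For each region, computes CorDiff and its permutation p-value separately
#' from the V1 and the S1 tracks (replicates c1, c2 vs kd1, kd2).  Regions
#' with a zero-variance vector in either enzyme are excluded (recorded in
#' the \code{skipped} attribute).
#'
#' @param x a normalized \linkS4class{ParsExperiment} with two replicates
#'   per condition/enzyme.
#' @param transcripts ids to scan (default all).
#' @param regions optional named list of c(start, end) 1-based intervals to
#'   restrict each transcript (exon-level grain); default whole transcript.
#' @param nPerm,seed permutation settings.
#' @return data.frame with one row per region: corDiffV1, pV1, corDiffS1,
#'   pS1 (see \code{\link{callSSC}} for the SSC flag).
#' @export
sscScan <- function(x, transcripts = transcriptIds(x), regions = NULL,
                    nPerm = 100L, seed = NULL) {
    out <- list(); skipped <- character()
    seeds <- .withSeed(seed, sample.int(2^30, length(transcripts)))
    for (i in seq_along(transcripts)) {
        tx <- transcripts[i]
        m <- trackMatrix(x, tx)
        if (!is.null(regions) && !is.null(regions[[tx]])) {
            rg <- regions[[tx]]
            m <- m[rg[1]:rg[2], , drop = FALSE]
        }
        cd <- colData(x)
        vec <- function(cond, enz, rep) {
            j <- which(cd$condition == cond & cd$enzyme == enz &
                       cd$replicate == rep)
            m[, j]
        }
        row <- list(region = tx)
        bad <- FALSE
        for (enz in c("V1", "S1")) {
            vs <- list(vec("control", enz, 1L), vec("control", enz, 2L),
                       vec("KD", enz, 1L), vec("KD", enz, 2L))
            if (any(vapply(vs, function(v) var(v) == 0, TRUE))) {
                bad <- TRUE; break
            }
            pp <- permutationP(vs[[1]], vs[[2]], vs[[3]], vs[[4]],
                               nPerm = nPerm, seed = seeds[i] + (enz == "S1"))
            row[[paste0("corDiff", enz)]] <- pp$observed
            row[[paste0("p", enz)]] <- pp$p
        }
        if (bad) { skipped <- c(skipped, tx); next }
        out[[length(out) + 1L]] <- as.data.frame(row,
                                                 stringsAsFactors = FALSE)
    }
    res <- if (length(out)) do.call(rbind, out) else
        data.frame(region = character(), corDiffV1 = numeric(),
                   pV1 = numeric(), corDiffS1 = numeric(), pS1 = numeric())
    attr(res, "skipped") <- skipped
    res
}

#' Call secondary-structure-changed (SSC) regions
#'
#' A region is SSC when CorDiff is positive in \emph{both} the V1 and the S1
#' comparison and the shuffle test is significant (empirical p below
#' \code{alpha} in both enzymes).
#'
#' @param results data.frame from \code{\link{sscScan}} (columns
#'   corDiffV1, pV1, corDiffS1, pS1).
#' @param alpha empirical significance level (default 0.05).
#' @return the input with an added logical \code{isSSC} column.
#' @export
callSSC <- function(results, alpha = 0.05) {
    need <- c("corDiffV1", "pV1", "corDiffS1", "pS1")
    miss <- !stats::complete.cases(results[, need])
    if (any(miss))
        message(sum(miss), " region(s) missing one enzyme; excluded")
    results$isSSC <- !miss & results$corDiffV1 > 0 & results$corDiffS1 > 0 &
        results$pV1 < alpha & results$pS1 < alpha
    results
}

#' Write SSC regions as BED with CorDiff and p columns
#'
#' @param results output of \code{\link{callSSC}}.
#' @param lengths named transcript lengths.
#' @param path output BED file (0-based half-open).
#' @return invisibly, \code{path}.
#' @export
writeSSCBed <- function(results, lengths, path) {
    sel <- results$isSSC
    lines <- sprintf("%s\t0\t%d\t%s\t0\t+\t%.4f\t%.3f\t%.4f\t%.3f",
                     results$region[sel], lengths[results$region[sel]],
                     results$region[sel], results$corDiffV1[sel],
                     results$pV1[sel], results$corDiffS1[sel],
                     results$pS1[sel])
    writeLines(lines, path)
    invisible(path)
}

#' Compare structural profiles of edited versus non-edited molecules
#'
#' Reads covering an edited adenosine are partitioned by the base observed
#' at the site (G = edited molecule, A = non-edited); per-partition
#' read-start vectors are built over a window around the site, and the
#' edited partition plays the role of one condition in a CorDiff /
#' permutation comparison.  Partitions need strictly more than
#' \code{minStarts} read starts in the window per replicate or the site is
#' skipped.  The relative PARS contrast is computed over the
#' \code{upstream} bases 5' of the site (read start and edited base must
#' share a read, so only upstream starts are informative).
#'
#' @param reads named list with elements \code{V1} and \code{S1}, each a
#'   list of two replicate data.frames with columns \code{start} and
#'   \code{baseAtSite} as produced by \code{\link{simulateReads}} (or parsed
#'   from alignments).
#' @param site 1-based transcript position of the edited adenosine.
#' @param window half-width of the profile window (default 50).
#' @param upstream number of bases upstream used for the relative PARS
#'   contrast (default 10).
#' @param minStarts coverage filter per partition per replicate (default 50,
#'   strict).
#' @param nPerm,seed permutation settings.
#' @return list with per-enzyme CorDiff results, the window profiles, and
#'   the mean upstream relative PARS per partition; or a list with
#'   \code{skipped = TRUE} and a \code{reason}.
#' @export
editedPartitionProfiles <- function(reads, site, window = 50L,
                                    upstream = 10L, minStarts = 50L,
                                    nPerm = 100L, seed = NULL) {
    offs <- (site - window):(site + window)
    profOne <- function(df, base) {
        sel <- !is.na(df$baseAtSite) & df$baseAtSite == base &
            df$start >= offs[1] & df$start <= offs[length(offs)]
        tabulate(df$start[sel] - offs[1] + 1L, nbins = length(offs))
    }
    profiles <- list()
    for (enz in c("V1", "S1")) {
        for (r in 1:2) {
            for (base in c("G", "A")) {
                v <- profOne(reads[[enz]][[r]], base)
                if (sum(v) <= minStarts)
                    return(list(skipped = TRUE,
                                reason = sprintf(
                                    "%s rep%d %s partition: %d read starts (need > %d)",
                                    enz, r, if (base == "G") "edited"
                                    else "non-edited", sum(v), minStarts)))
                profiles[[paste(enz, r, base, sep = "_")]] <- v
            }
        }
    }
    out <- list(skipped = FALSE, profiles = profiles)
    for (enz in c("V1", "S1")) {
        pp <- permutationP(profiles[[paste(enz, 1, "G", sep = "_")]],
                           profiles[[paste(enz, 2, "G", sep = "_")]],
                           profiles[[paste(enz, 1, "A", sep = "_")]],
                           profiles[[paste(enz, 2, "A", sep = "_")]],
                           nPerm = nPerm, seed = seed)
        out[[paste0("corDiff", enz)]] <- pp$observed
        out[[paste0("p", enz)]] <- pp$p
    }
    up <- (window - upstream + 1L):window   # offsets -upstream..-1
    relMean <- function(base) {
        tr <- list(V1_1 = profiles[[paste("V1", 1, base, sep = "_")]],
                   V1_2 = profiles[[paste("V1", 2, base, sep = "_")]],
                   S1_1 = profiles[[paste("S1", 1, base, sep = "_")]],
                   S1_2 = profiles[[paste("S1", 2, base, sep = "_")]])
        rp <- relativeProfile(tr, pseudocount = 1 / length(offs))
        mean(rp$relativePars[up])
    }
    out$relativeParsUpstream <- c(edited = relMean("G"),
                                  nonEdited = relMean("A"))
    out
}
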