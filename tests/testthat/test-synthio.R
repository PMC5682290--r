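# Synthetic transcriptome, editing and digestion generator.

test_that("identical config and seed give byte-identical output", {
    cfg <- tinyConfig()
    a <- makeTranscriptome(cfg)
    b <- makeTranscriptome(cfg)
    expect_identical(vapply(a$transcripts, function(t) t@seq, ""),
                     vapply(b$transcripts, function(t) t@seq, ""))
    expect_identical(a$truth, b$truth)
    ea <- simulateExperiment(cfg)
    eb <- simulateExperiment(cfg)
    expect_identical(SummarizedExperiment::assay(ea$experiment, "counts"),
                     SummarizedExperiment::assay(eb$experiment, "counts"))
})

test_that("pair map is symmetric and edit sites sit on adenosines", {
    sim <- .tinySim()
    for (t in sim$transcripts) {
        pm <- t@pairMap
        idx <- which(!is.na(pm))
        expect_identical(pm[pm[idx]], idx)
        es <- t@editSites
        if (nrow(es)) {
            expect_true(all(substring(t@seq, es$pos, es$pos) == "A"))
            expect_true(all(es$levelKD <= es$levelControl))
            expect_true(all(es$levelControl >= 0 & es$levelControl <= 1))
        }
    }
    # every transcript appears exactly once in the truth table
    expect_identical(anyDuplicated(sim$truth$transcripts$transcript), 0L)
    expect_length(sim$transcripts, nrow(sim$truth$transcripts))
})

test_that("zero mismatch rate gives perfect arms and no A:C sites", {
    cfg <- tinyConfig(armMismatchRate = 0)
    tr <- makeTranscriptome(cfg)
    for (t in tr$transcripts) {
        idx <- which(!is.na(t@pairMap))
        bases <- strsplit(t@seq, "")[[1]]
        comp <- chartr("ACGU", "UGCA", paste(bases[idx], collapse = ""))
        expect_identical(paste(bases[t@pairMap[idx]], collapse = ""), comp)
        expect_false(any(t@editSites$context == "AC"))
    }
})

test_that("arms that cannot fit are an invalid-config error", {
    cfg <- tinyConfig(armLength = 400L, lengthRange = c(900L, 901L))
    expect_error(makeTranscriptome(cfg), "invalid config")
})

test_that("realized arm mismatch fraction is inside the binomial 99% CI", {
    cfg <- simulationConfig(nTranscripts = 100L, armMismatchRate = 0.15,
                            seed = 202L)
    tr <- makeTranscriptome(cfg)
    mismatches <- 0L; trials <- 0L
    for (t in tr$transcripts) {
        bases <- strsplit(t@seq, "")[[1]]
        arm1 <- which(!is.na(t@pairMap))[seq_len(cfg@armLength)]
        comp <- strsplit(chartr("ACGU", "UGCA",
                                paste(bases[arm1], collapse = "")), "")[[1]]
        mismatches <- mismatches + sum(bases[t@pairMap[arm1]] != comp)
        trials <- trials + cfg@armLength
    }
    ci <- qbinom(c(0.005, 0.995), trials, 0.15)
    expect_gte(mismatches, ci[1])
    expect_lte(mismatches, ci[2])
})

test_that("editing rule: I:C pairs, I:U unpairs, Bernoulli per molecule", {
    t1 <- toyDuplex(levelAC_control = 1, levelAU_control = 1)
    ens <- realizeMolecules(t1, "control", 50L, seed = 1L)
    expect_true(all(ens$paired[1, ]))   # edited A:C -> I:C paired
    expect_true(all(ens$paired[10, ]))
    expect_false(any(ens$paired[4, ]))  # edited A:U -> I:U unpaired
    expect_false(any(ens$paired[7, ]))
    # unedited baseline is the reverse
    base <- basePairedState(t1)
    expect_false(base[1]); expect_true(base[4])
    # Bernoulli(level): edited fraction at level 0.5 within binomial 99% CI
    t2 <- toyDuplex(levelAC_control = 0.5, levelAC_kd = 0.15)
    ens2 <- realizeMolecules(t2, "control", 10000L, seed = 2L)
    ci <- qbinom(c(0.005, 0.995), 10000L, 0.5)
    expect_gte(sum(ens2$edited[1, ]), ci[1])
    expect_lte(sum(ens2$edited[1, ]), ci[2])
    expect_error(realizeMolecules(t1, "treated", 5L), "condition")
})

test_that("digestion conserves depth and respects rate degeneracies", {
    cfg <- tinyConfig()
    t1 <- toyDuplex()
    ens <- realizeMolecules(t1, "control", 100L, seed = 3L)
    counts <- simulateDigestion(ens, "V1", 5000L, cfg, seed = 4L)
    expect_identical(sum(counts), 5000L)
    expect_error(simulateDigestion(ens, "V1", 0L, cfg), "depth")
    expect_error(simulateDigestion(ens, "X1", 10L, cfg), "enzyme")
    # fully paired molecule set, S1 with zero DS rate -> zero reads
    allPaired <- ens
    allPaired$paired[] <- TRUE
    cfg0 <- tinyConfig(s1DsRate = 0, v1SsRate = 0)
    expect_identical(sum(simulateDigestion(allPaired, "S1", 1000L, cfg0,
                                           seed = 5L)), 0L)
    v1 <- simulateDigestion(allPaired, "V1", 1000L, cfg0, seed = 6L)
    expect_identical(sum(v1), 1000L)  # V1 reads spread over all (DS) bases
})

test_that("uniform weights give multinomial-uniform counts (chi-square)", {
    t1 <- toyDuplex()
    ens <- realizeMolecules(t1, "control", 10L, seed = 7L)
    ens$paired[] <- FALSE                       # all bases single-stranded
    cfg <- tinyConfig()
    counts <- simulateDigestion(ens, "S1", 24000L, cfg, seed = 8L)
    expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("raising an A:U site's editing level lowers its V1 weight share", {
    cfg <- tinyConfig()
    shares <- vapply(c(0.1, 0.5, 0.9), function(lvl) {
        t1 <- toyDuplex(levelAU_control = lvl, levelAU_kd = 0.1 * lvl)
        ens <- realizeMolecules(t1, "control", 20000L, seed = 9L)
        w <- parsdiff:::.digestWeights(ens, "V1", cfg)
        w[4] / sum(w)
    }, 0)
    expect_true(all(diff(shares) < 0))
})

test_that("deep digestion of a hairpin yields PARS > 0 on the stem and < 0 on the loop", {
    cfg <- tinyConfig(armMismatchRate = 0)
    tr <- makeTranscriptome(cfg)
    t1 <- tr$transcripts[[1]]
    ens <- realizeMolecules(t1, "control", 50L, seed = 10L)
    v1 <- simulateDigestion(ens, "V1", 2e5L, cfg, seed = 11L)
    s1 <- simulateDigestion(ens, "S1", 2e5L, cfg, seed = 12L)
    score <- parsScore(v1, s1)
    paired <- basePairedState(t1)
    expect_gt(mean(score[paired]), 0)
    expect_lt(mean(score[!paired]), 0)
})

test_that("fixtures round-trip losslessly and cover all eight samples", {
    sim <- .tinySim()
    dir <- withr::local_tempdir()
    files <- emitFixtures(sim$transcripts, sim$experiment, sim$truth, dir)
    tracks <- list.files(dir, pattern = "\\.track\\.tsv$")
    expect_length(tracks, 8L)   # 2 conditions x 2 enzymes x 2 replicates
    pe2 <- readTracks(dir)
    m1 <- SummarizedExperiment::assay(sim$experiment, "counts")
    m2 <- SummarizedExperiment::assay(pe2, "counts")
    expect_equal(unname(m1[, order(colnames(m1))]),
                 unname(m2[, order(colnames(m2))]))
    fa <- Biostrings::readDNAStringSet(file.path(dir, "sequences.fa"))
    expect_identical(unname(as.character(fa[1])),
                     chartr("U", "T", sim$transcripts[[1]]@seq))
})

test_that("an empty transcript list still emits valid empty files", {
    dir <- withr::local_tempdir()
    emitFixtures(list(), NULL, list(), dir)
    expect_true(file.exists(file.path(dir, "sequences.fa")))
    expect_identical(length(readLines(file.path(dir, "models.bed"))), 0L)
})
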