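# Editing-level quantification, DES, hyper-editing criteria, pairing context.

mkPileups <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
        data.frame(transcript = r[["tx"]], pos = as.integer(r[["pos"]]),
                   strand = "+", condition = r[["cond"]],
                   replicate = as.integer(r[["rep"]]),
                   A = as.integer(r[["A"]]), C = 0L,
                   G = as.integer(r[["G"]]), T = 0L,
                   stringsAsFactors = FALSE)))
}

test_that("editing levels are G/(A+G) on the annotated strand, pooled", {
    p <- mkPileups(list(tx = "t", pos = 5, cond = "control", rep = 1,
                        A = 8, G = 2),
                   list(tx = "t", pos = 5, cond = "KD", rep = 1,
                        A = 10, G = 0))
    p$C[1] <- 7L; p$T[1] <- 3L    # other bases at the site are ignored
    sites <- data.frame(transcript = "t", pos = 5L, strand = "+")
    e <- callEditing(p, sites)
    expect_equal(e$levelControl, 0.2)
    expect_equal(e$levelKD, 0)
    expect_error(callEditing(p, data.frame(transcript = "t", pos = 5L,
                                           strand = NA)),
                 "strand")
    # replicates pool within condition
    p2 <- rbind(p, mkPileups(list(tx = "t", pos = 5, cond = "control",
                                  rep = 2, A = 2, G = 8)))
    expect_equal(callEditing(p2, sites)$levelControl, 0.5)
})

test_that("DES calls are one-sided lower-in-KD with Fisher oracle agreement", {
    sites <- data.frame(transcript = c("a", "b", "c"), pos = 1:3,
                        strand = "+",
                        aControl = c(50, 50, 95), gControl = c(50, 50, 5),
                        aKD = c(95, 50, 50), gKD = c(5, 50, 50),
                        levelControl = c(0.5, 0.5, 0.05),
                        levelKD = c(0.05, 0.5, 0.5))
    des <- callDES(sites)
    expect_true(des$isDES[1])
    # identical counts: one-sided p includes the observed mass (> 0.5)
    expect_false(des$isDES[2]); expect_gt(des$p[2], 0.5)
    expect_false(des$isDES[3]); expect_true(des$higherInKD[3])
    oracle <- fisher.test(matrix(c(50, 5, 50, 95), 2),
                          alternative = "greater")$p.value
    expect_equal(des$p[1], oracle)
    # z-test flag gives the same qualitative calls here
    desZ <- callDES(sites, test = "ztest")
    expect_identical(desZ$isDES, des$isDES)
})

test_that("hyper-edited read criteria follow the density and purity rules", {
    mkRead <- function(len, nAG, nOther, qual = 35L) {
        mm <- data.frame(
            ref = c(rep("A", nAG), rep("C", nOther)),
            alt = c(rep("G", nAG), rep("T", nOther)),
            qual = qual)
        list(length = len, mismatches = mm)
    }
    out <- hyperEditReadFilter(list(
        mkRead(100L, 6L, 0L),          # 6 >= 5 and 100% > 90% -> pass
        mkRead(100L, 4L, 0L),          # 4 < 5 -> fail
        mkRead(100L, 10L, 2L)))        # 10/12 ~ 83% <= 90% -> fail
    expect_identical(out$pass, c(TRUE, FALSE, FALSE))
    # low-quality A-to-G do not count toward the density rule
    lowq <- mkRead(100L, 6L, 0L, qual = 20L)
    expect_false(hyperEditReadFilter(list(lowq))$pass)
    noq <- list(length = 50L,
                mismatches = data.frame(ref = "A", alt = "G",
                                        qual = NA_integer_))
    expect_error(hyperEditReadFilter(list(noq)), "qualities")
})

test_that("hyper-edit decisions match a brute-force recount on random reads", {
    set.seed(31)
    reads <- lapply(1:60, function(i) {
        len <- sample(40:120, 1)
        n <- sample(0:12, 1)
        mm <- data.frame(
            ref = sample(c("A", "C", "G", "T"), n, TRUE,
                         prob = c(0.6, 0.2, 0.1, 0.1)),
            alt = sample(c("G", "T", "A"), n, TRUE, prob = c(0.7, 0.2, 0.1)),
            qual = sample(20:40, n, TRUE))
        list(length = len, mismatches = mm)
    })
    out <- hyperEditReadFilter(reads)
    for (i in seq_along(reads)) {
        mm <- reads[[i]]$mismatches
        ag <- mm$ref == "A" & mm$alt == "G"
        expected <- sum(ag & mm$qual >= 30) >= 0.05 * reads[[i]]$length &&
            sum(ag) > 0.9 * nrow(mm)
        expect_identical(out$pass[i], expected)
    }
})

test_that("pairing-context classes and the observed-vs-expected contrast", {
    t1 <- toyDuplex()
    pc <- pairContext(c(1L, 4L), t1@pairMap, t1@seq)
    expect_identical(pc$class, c("AC", "AU"))
    # unpaired adenosines are 'other' and excluded from the AC/AU contrast
    pc2 <- pairContext(c(1L, 5L), t1@pairMap, t1@seq)
    expect_identical(pc2$class[2], "other")
    expect_error(pairContext(2L, t1@pairMap, t1@seq), "adenosine")
    # seeding edits preferentially at A:C raises observed above expected
    cfg <- tinyConfig(nTranscripts = 8L, fracSWE = 1, fracDSWE = 0,
                      seed = 505L)
    tr <- makeTranscriptome(cfg)
    obs <- exp <- n <- 0
    ps <- c()
    for (t in tr$transcripts) {
        if (!nrow(t@editSites)) next
        pc <- pairContext(t@editSites$pos, t@pairMap, t@seq)
        obs <- obs + sum(pc$class == "AC")
        n <- n + sum(pc$class %in% c("AC", "AU"))
        exp <- exp + pc$expectedAC
        ps <- c(ps, pc$p)
    }
    expect_gt(obs / n, exp / length(ps))   # pooled observed > mean expected
    expect_lt(min(ps), 0.05)
    # classes partition the sites
    expect_identical(sum(pc$class %in% c("AC", "AU", "other")),
                     length(pc$class))
})

test_that("level-by-context filters strictly and recovers planted means", {
    sites <- data.frame(level = c(0.3, 0.4, 0.2, 0.25),
                        coverage = c(5, 6, 10, 12),
                        class = c("AC", "AC", "AU", "AU"))
    out <- levelByContext(sites, minCov = 5L)
    expect_identical(out$summary$n, c(1L, 2L))    # coverage 5 excluded
    expect_error(levelByContext(sites[sites$class == "AU", ]), "AC")
    sameLvl <- data.frame(level = rep(c(0.1, 0.2, 0.3), 2),
                          coverage = 10,
                          class = rep(c("AC", "AU"), each = 3))
    expect_equal(levelByContext(sameLvl)$p, 1)
    # recovery at depth 100: planted means 0.16 (A:C) vs 0.10 (A:U)
    set.seed(32)
    nS <- 400L
    lvlAC <- parsdiff:::.rbetaMS(nS, 0.16, 0.08)
    lvlAU <- parsdiff:::.rbetaMS(nS, 0.10, 0.05)
    g <- rbinom(2 * nS, 100L, c(lvlAC, lvlAU))
    est <- data.frame(level = g / 100,
                      coverage = 100L,
                      class = rep(c("AC", "AU"), each = nS))
    out2 <- levelByContext(est)
    expect_equal(out2$summary$mean[out2$summary$class == "AC"], 0.16,
                 tolerance = 0.02 / 0.16)
    expect_equal(out2$summary$mean[out2$summary$class == "AU"], 0.10,
                 tolerance = 0.02 / 0.10)
    expect_lt(out2$p, 1e-10)
})

test_that("structure-editing rank correlation behaves at the extremes", {
    x <- setNames((1:20) / 20, paste0("t", 1:20))
    y <- x^2
    out <- editingStructureCorrelation(x, y)
    expect_equal(out$rho, 1)
    set.seed(33)
    indep <- editingStructureCorrelation(
        setNames(runif(200), paste0("t", 1:200)),
        setNames(runif(200), paste0("t", 1:200)))
    expect_lt(abs(indep$rho), 0.2)
    coupled <- editingStructureCorrelation(x, setNames(
        x + rnorm(20, 0, 0.1), names(x)))
    expect_gt(coupled$rho, 0)
    expect_error(editingStructureCorrelation(x[1:5], y[1:5]), ">= 10")
    expect_error(editingStructureCorrelation(
        setNames(rep(1, 20), names(x)), y), "constant")
})
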