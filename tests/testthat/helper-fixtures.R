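# Shared fixtures built in code.

# small but complete simulated experiment (cached per session)
tinyConfig <- function(...) {
    args <- utils::modifyList(list(nTranscripts = 6L, seed = 101L),
                              list(...))
    do.call(simulationConfig, args)
}

.tinySim <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) cache <<- simulateExperiment(tinyConfig())
        cache
    }
})

# hand-built duplex transcript: a 12-nt toy with a 4-bp register,
# one A:C-context site (pos 1 <-> 10) and one A:U-context site (pos 4 <-> 7)
toyDuplex <- function(levelAC_control = 1, levelAC_kd = 0.3,
                      levelAU_control = 1, levelAU_kd = 0.3) {
    seq <- c("A", "G", "C", "A", "A", "A", "U", "G", "C", "C", "G", "G")
    pm <- rep(NA_integer_, 12L)
    pm[1:4] <- 10:7; pm[7:10] <- 4:1
    new("SyntheticTranscript", id = "toy",
        seq = paste(seq, collapse = ""), pairMap = pm,
        editSites = data.frame(
            pos = c(1L, 4L), partner = c(10L, 7L),
            context = c("AC", "AU"),
            levelControl = c(levelAC_control, levelAU_control),
            levelKD = c(levelAC_kd, levelAU_kd),
            stringsAsFactors = FALSE),
        regionLabels = c(rep("IR_arm", 4), "3UTR", "3UTR",
                         rep("IR_arm", 4), "3UTR", "3UTR"))
}

# longer hand-built duplex (length 140, 30-bp arms at 40..69 / 90..119)
# with a single editing site at position 61; context "AC" makes editing
# pair the site, "other" (A:G mismatch) makes editing structurally inert
toyDuplexLong <- function(levelControl = 0.5, context = "AC") {
    set.seed(77)
    L <- 140L
    seq <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
    arm1 <- 40:69; arm2 <- 90:119
    pm <- rep(NA_integer_, L)
    pm[arm1] <- rev(arm2); pm[arm2] <- rev(arm1)
    seq[rev(arm2)] <- strsplit(chartr("ACGU", "UGCA",
                                      paste(seq[arm1], collapse = "")),
                               "")[[1]]
    seq[61] <- "A"
    seq[pm[61]] <- if (context == "AC") "C" else "G"
    new("SyntheticTranscript", id = "toyLong",
        seq = paste(seq, collapse = ""), pairMap = pm,
        editSites = data.frame(pos = 61L, partner = pm[61],
                               context = context,
                               levelControl = levelControl,
                               levelKD = 0.3 * levelControl,
                               stringsAsFactors = FALSE),
        regionLabels = replace(rep("3UTR", L), c(arm1, arm2), "IR_arm"))
}

# build a ParsExperiment directly from a bases-x-samples matrix over one
# transcript with the standard 2x2x2 sample layout
peFromMatrix <- function(m, transcript = "tx") {
    layout <- expand.grid(replicate = 1:2, enzyme = c("V1", "S1"),
                          condition = c("control", "KD"),
                          stringsAsFactors = FALSE)
    stopifnot(ncol(m) == nrow(layout))
    ParsExperiment(m, transcript = rep(transcript, nrow(m)),
                   pos = seq_len(nrow(m)),
                   condition = layout$condition, enzyme = layout$enzyme,
                   replicate = layout$replicate)
}

# independent two-pass CorDiff oracle written from the definition
corDiffOracle <- function(c1, c2, kd1, kd2) {
    pearson <- function(x, y) {
        n <- length(x)
        sx <- sum(x); sy <- sum(y)
        num <- n * sum(x * y) - sx * sy
        den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
        num / den
    }
    pearson(c1, c2)^2 + pearson(kd1, kd2)^2 -
        pearson(c1, kd1)^2 - pearson(c2, kd2)^2
}
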