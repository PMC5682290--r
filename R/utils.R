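# Internal helpers shared across modules.

# Evaluate expr with a locally-set RNG seed; the caller's RNG state is
# restored afterwards so library code never perturbs user randomness.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

.RNA_BASES <- c("A", "C", "G", "U")

# Watson-Crick complement on the RNA alphabet.
.rnaComplement <- function(x) {
    chartr("ACGU", "UGCA", x)
}

# Split a sequence string into a character vector of bases.
.charVec <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# DNA-alphabet input is accepted everywhere sequences enter; internally the
# RNA alphabet is used.
.toRNA <- function(seq) chartr("Tt", "Uu", toupper(seq))
.toDNA <- function(seq) chartr("Uu", "Tt", seq)

# Beta draws parameterised by mean and sd (sd shrunk if infeasible).
.rbetaMS <- function(n, mean, sd) {
    v <- min(sd^2, mean * (1 - mean) * 0.95)
    k <- mean * (1 - mean) / v - 1
    stats::rbeta(n, mean * k, (1 - mean) * k)
}
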