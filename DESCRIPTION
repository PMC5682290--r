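Package: parsdiff
Title: Differential RNA Secondary Structure Analysis from PARS-seq Under
    A-to-I Editing Perturbation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing parallel analysis of RNA structure (PARS-seq)
    nuclease-probing experiments that compare RNA secondary structure between
    control and ADAR1-knockdown conditions. Converts strand-specific alignments
    into per-base read-start tracks, computes PARS scores, classifies bases as
    double- or single-stranded by exact enrichment tests, detects structurally
    changed regions with a correlation-difference permutation statistic,
    quantifies differential A-to-I editing and its duplex pairing context,
    derives folding constraints, and relates structural change to translation
    efficiency. Includes a seeded simulator of condition-dependent editing and
    V1/S1 digestion with known ground truth for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Transcriptomics, RNASeq, StructuralPrediction, Software
RoxygenNote: 7.3.3
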