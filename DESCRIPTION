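Package: ednahap
Title: Haplotype Calling and Population Differentiation from Seawater
    eDNA Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested implementation of an environmental-DNA (eDNA)
    amplicon haplotyping workflow for cetacean mitochondrial control
    region sequences. Paired-end reads are primer/adapter trimmed,
    quality filtered, merged, dereplicated and length filtered; PCR
    chimeras are removed with a deterministic two-parent crossover
    detector; a per-run error-frequency threshold is calibrated from
    positive-control libraries of known haplotype and applied to
    per-sample unique-sequence frequencies; retained sequences are
    assigned to a reference haplotype database by global pairwise
    alignment, with rules for novel and secondary haplotypes.
    Downstream, haplotype-by-stratum differentiation is tested with
    AMOVA-based Phi-ST and chi-squared statistics (permutation
    p-values), and species-specific qPCR detections are quantified
    against a relative standard curve. A built-in simulator generates
    reference databases, paired-end FASTQ reads with known truth, and
    qPCR plates, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
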