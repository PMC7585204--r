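Package: mtspectra
Title: Mitochondrial DNA Mutation-Spectrum Analysis on Circular Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A PCR-free style mitochondrial DNA (mtDNA) mutation-spectrum
    pipeline for circular genomes. Extracts single-nucleotide variants and
    deletions from read alignments against a doubled circular reference,
    classifies deletions versus very-long-range deletions (multimers),
    computes direct-repeat and breakpoint-homology statistics against
    randomized length-matched null libraries, summarises positional spectra
    (binned sharing, allele-fraction profiles, per-gene loads), and provides
    the cohort statistics layer (normality-gated location tests, factorial
    ANOVA with Tukey post hoc, Bonferroni correction, and an exact multi-set
    intersection test). Includes a seeded synthetic-data generator emitting
    circular genomes, planted variants, SAM alignments and cohort designs
    with known truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    car,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
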