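Package: hapsel
Title: Purifying Selection on Haploid and Diploid Tissue-Specific Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for comparing the strength of purifying selection between
    genes specifically expressed in haploid and diploid tissues. From dual-ploidy
    variant calls of a haploid cohort, a reference with gene models, and a
    tissue expression matrix, the package masks collapsed paralogs, applies
    genotype and site filters, classifies coding positions by codon degeneracy
    (0-fold/4-fold), computes the tau tissue-specificity index, estimates
    missing-data-aware nucleotide diversity with invariant sites, builds folded
    site frequency spectra by replicate hypergeometric downsampling, fits a
    gamma distribution of fitness effects under a two-epoch demographic model
    by Poisson likelihood, and compares gene sets through the kernel-density
    overlap of the fitted gamma shape parameter. A synthetic-data module
    generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
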