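Package: sigseg
Title: Regional Mutational Signature Activity Profiles by Optimal Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates mutational-signature activities along the genome from
    somatic single-base substitutions. Mutations are classified into the 96
    trinucleotide substitution channels, aggregated into equal-count genomic
    bins, and modelled as a mixture of multinomial signatures whose mixture
    coefficients (activities) are fitted by expectation-maximization.
    Changepoints in regional activity are detected by PELT optimal
    segmentation with a BIC penalty, and their placement is characterized by
    within-bin bootstrap resampling, cohort-level recurrence analysis via
    kernel density ranges and sliding windows, kataegis detection, and
    randomization tests of association between changepoints and genomic
    feature tracks (copy-number aberrations, TAD boundaries, chromatin
    accessibility, compartments, replication timing, gene density). A
    synthetic-data module simulates genomes with planted piecewise-constant
    activity regimes for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
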