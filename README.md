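# sigseg — regional mutational signature activity profiles

Somatic mutations in a cancer genome are generated by multiple mutagenic
processes, each leaving a characteristic distribution over the 96
single-base-substitution (SBS96) channels — a *mutational signature*. Most
signature analyses fit one activity (exposure) vector per sample, implicitly
assuming the mix of processes is constant along the genome. `sigseg` drops
that assumption: it estimates signature activities *regionally* and finds
the chromosomal positions where they change.

The package is for cancer-genomics analysts working with somatic SNV calls
(VCF or tabular) and a COSMIC-style signature reference, who want to know
whether — and where — the mutational composition of a genome shifts, and
whether those shifts line up across a cohort or with genomic features.

## Model and algorithm

Mutations are classified into the 96 channels (pyrimidine-strand
trinucleotide convention), ordered by chromosomal coordinate, and grouped
into bins of equal mutation count (default 100). The channel counts of a
region are modelled as a mixture of multinomials,

&nbsp;&nbsp; p(channel k) = Σₛ πₛ μₛₖ,

where μₛ are the reference signatures and π the regional activities, fitted
by EM (the likelihood is concave in π for fixed μ). Changepoints are found
by PELT optimal segmentation of the bin sequence, minimizing

&nbsp;&nbsp; Σ_segments −2 log L + β · #changepoints,&nbsp;&nbsp; β = (S−1) log N (BIC),

subject to one-bin minimum segments and no adjacent-bin changepoints. Each
changepoint gets a magnitude (cosine distance of flanking activity
vectors), bootstrap support (within-bin resampling), and optionally a
cohort-level recurrence analysis (KDE location ranges + sliding-window
counting), kataegis calls (≥ 6 consecutive mutations, mean gap ≤ 1 kb), and
two randomization tests of association with feature tracks (overlap test;
changepoint-vs-flank distribution test with KS/Fisher inner statistics and
an empirical null of p-values).

A first-class simulation module (`simulate_sample()`, `synthetic_catalog()`)
plants known activity regimes, kataegis clusters, and feature tracks, and
backs the test suite and the acceptance bench.

## Worked example

Simulate a 2,000-mutation genome with a planted activity switch at 100 Mb,
profile it, and bootstrap the changepoint:

```r
library(sigseg)
catalog <- synthetic_catalog(4, overlap = 0.15)
layout  <- genome_layout("1", 2e8)
segs    <- data.frame(chrom = "1", start = c(0, 1e8), end = c(1e8, 2e8))
act     <- rbind(c(0.45, 0.30, 0.15, 0.10),
                 c(0.15, 0.15, 0.30, 0.40))
cfg     <- simulation_config(layout, catalog, segs, act,
                             n_mutations = 2000, seed = 42)
sim     <- simulate_sample(cfg)

profile <- run_profile(sim$mutations, catalog, bin_size = 100, mode = "genome")
profile
#> signature_profile (genome-wise): 20 bins, 2 segment(s), 1 changepoint(s)
profile$changepoints
#>   boundary chrom    start       end cross_chrom magnitude support
#> 1       10     1 92063073 112237791       FALSE 0.3118333      NA
round(profile$activity, 3)
#>       SYN1  SYN2  SYN3  SYN4
#> [1,] 0.457 0.272 0.163 0.108
#> [2,] 0.168 0.161 0.281 0.391
```

The segmentation recovers the planted switch: one changepoint, between bins
10 and 11, whose reported region (92–112 Mb, the union of the two flanking
bins' spans) contains the true boundary at 100 Mb, with fitted activities
close to the planted (0.45, 0.30, 0.15, 0.10) and (0.15, 0.15, 0.30, 0.40)
and a magnitude of 0.31 (cosine distance between the two fitted vectors).

```r
report <- bootstrap_profile(sim$mutations, catalog, bin_size = 100,
                            mode = "genome", n_bootstraps = 5, seed = 1)
report$table
#>   boundary chrom    start       end magnitude n_found support high_confidence
#> 1       10     1 92063073 112237791 0.3118333       5       1            TRUE
```

All five bootstrap replicates replace the changepoint within one bin
(support = 1): a high-confidence call.

A thin command-line wrapper is installed with the package
(`system.file("cli", "gts.R", package = "sigseg")`) with subcommands
`profile`, `bootstrap`, `kataegis`, `recur`, and `simulate`.

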