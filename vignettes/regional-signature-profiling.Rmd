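---
title: "Regional mutational signature profiling with sigseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional mutational signature profiling with sigseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigseg)
```

## The model

Somatic single-base substitutions carry two pieces of information: where
they fall in the genome and what they look like. The "look" is summarized
by the SBS96 catalog: each substitution is represented on the pyrimidine
strand as one of 6 substitution classes x 16 trinucleotide contexts = 96
channels. A mutational signature is a probability distribution $\mu_s$
over these channels, and a region of the genome is modelled as a mixture
of multinomials,

$$ p(\text{channel } k) \;=\; \sum_{s=1}^{S} \pi_s \,\mu_{sk}, $$

where the mixture coefficients $\pi$ are the *signature activities* of
the region — the fraction of its mutations attributed to each mutagenic
process. Because the per-mutation likelihood factorizes over channels,
the channel counts of a region are a sufficient statistic, and the
multinomial coefficient (constant in $\pi$) is dropped everywhere: all
comparisons use the categorical log-likelihood
$\sum_k c_k \log \sum_s \pi_s \mu_{sk}$.

Activities are estimated with EM (`em_fit()`). The E-step computes the
responsibility $\pi_s \mu_{sk} / \sum_t \pi_t \mu_{tk}$ of signature $s$
for channel $k$; the M-step sets each activity to the count-weighted mean
responsibility. With the emissions fixed, this likelihood is concave in
$\pi$, so the uniform initialization $\pi_s = 1/S$ is sufficient and no
restarts are needed. Convergence is declared when the log-likelihood
improves by less than `tol = 1e-6` (cap `max_iter = 1000`), and the
log-likelihood trace is asserted non-decreasing on every fit. Activities
are allowed to hit exactly zero: the M-step can reach the boundary and
near-zero activities are meaningful output, so no floor is applied.

## Binning and segmentation

Mutations are sorted by chromosomal coordinate and grouped into bins of
equal mutation count (default `bin_size = 100`, the smallest size at
which per-bin activity estimates are stable; 150–300 behave similarly
and trade resolution for speed). Binning is either *chromosome-wise*
(each chromosome binned and segmented independently — the recommended
mode for well-powered samples) or *genome-wise* (chromosomes laid
end-to-end in the order 1–22, X, Y — useful below ~100 mutations per
chromosome). The terminal bin absorbs any remainder, so it may exceed
`bin_size`; a chromosome with fewer than `bin_size` mutations is kept as
a single undersized bin with a warning rather than dropped silently.
A bin's genomic span is taken to run from its first to its last mutation
— the boundary between adjacent bins is genuinely uncertain at the scale
of the gap between them, and all downstream interval logic (changepoint
regions, overlap tests) widens boundaries to the union of the two
flanking bins' spans for exactly this reason.

Changepoints are found by minimizing, over all segmentations of the bin
sequence,

$$ \sum_{\text{segments}} -2\log L(\text{segment}) \;+\;
   \beta \cdot \#\text{changepoints}, $$

with PELT, a pruned dynamic program whose pruning is exact here because
segment costs are superadditive (pooling data never beats fitting the
parts separately). Two structural constraints are built into the
recursion rather than applied post hoc: every segment contains at least
one bin, and no two changepoints may sit at adjacent bins (boundaries
differ by at least two). The adjacency constraint has one subtle
interaction with PELT pruning: the standard domination argument compares
a candidate against a boundary at the current endpoint, which is itself
inadmissible at the very next endpoint; pruned candidates are therefore
retired with a one-step delay, which restores exactness (verified against
exhaustive enumeration in the test suite).

The default penalty is the BIC charge for the $S-1$ free mixture
parameters an extra segment introduces, $\beta = (S-1)\log N$ on the
$-2\log L$ scale, with $N$ the number of mutations in the series being
segmented (per chromosome in chromosome-wise mode). The exact constant is
a modelling choice — reasonable alternatives exist (counting bins rather
than mutations, per-segment rather than per-parameter accounting) — so it
is exposed as a `penalty_scale` multiplier. With a single signature there
is no free mixture parameter and no changepoint is identifiable; the
penalty is infinite and a warning is raised.

The magnitude of a changepoint is the cosine distance between the
activity vectors fitted on its two flanking segments, which lies in
$[0, 1]$ for non-negative activities and is invariant to scaling.

## Confidence and cohort analyses

**Bootstrap.** Bin boundaries are held fixed and the mutations within
each bin are resampled with replacement (equivalently, each bin's channel
counts are redrawn multinomially at the same bin size); the segmentation
is re-run and a baseline changepoint's support is the fraction of
replicates placing a changepoint within one bin of it. The one-bin
matching tolerance reflects that bin-level jitter is expected;
support is monotone non-increasing as the tolerance shrinks. Changepoints
found in more than one bootstrap replicate are flagged high-confidence.
Defaults are 5 bootstraps for profiles and 20 for the cohort resampling
protocol (`resample_robustness()`). In genome-wise mode the concatenation
order is a convention, so `chromosome_order_shuffle()` additionally
re-bins under a random chromosome permutation.

**Recurrence.** Each changepoint's location evidence (its boundary
midpoint across bootstrap replicates, falling back to the flanking-bin
span when degenerate) is summarized by a Gaussian KDE with Silverman's
rule-of-thumb bandwidth; the changepoint's *range* is the KDE mean plus
or minus one standard deviation of the density (sample spread inflated by
the bandwidth), clipped to the chromosome. Ranges from a cohort are
overlaid and windows of 1 Mb, stepped every 0.5 Mb, are scanned for
windows where at least `threshold = 7` distinct samples overlap; maximal
runs of qualifying windows are merged and each region is reported
centered at its maximum-count window (leftmost on ties, for determinism).
The window size and step are package choices: recurrent regions of
interest span several megabases, so 1 Mb windows resolve them; both are
arguments.

**Kataegis.** An event is a maximal run of at least 6 consecutive
mutations with mean inter-mutation distance at most 1,000 bp. The
criterion fixes neither an algorithm nor uniqueness, so the package makes
the output unique by taking all qualifying windows of consecutive
mutations and merging overlapping ones into their maximal extension; the
result provably cannot be extended by one adjacent mutation, and events
never overlap. The implementation reduces the window criterion to
$z_j \le z_i$ with $z_m = \mathrm{pos}_m - 1000\,m$, and is tested
against a brute-force scan over all windows.

**Association tests.** Two randomization frameworks ask whether
changepoints co-locate with genomic features. The *overlap test* compares
the proportion of changepoints whose region touches a feature against the
same proportion in random changepoint sets of equal size, drawn uniformly
from the profile's admissible bin boundaries (without replacement,
non-adjacent — null sets should be admissible segmentations, so the same
constraints apply; sampling uses the gap-constrained subset bijection, so
it is exactly uniform). The *flank test* compares the distribution of a
feature between a changepoint-containing segment and an equally sized
flank centered on the nearest changepoint (or chromosome boundary) in
each direction, using a two-sided Kolmogorov–Smirnov test for continuous
features and Fisher's exact test on event counts for discrete ones, and
refers the resulting p-value to an empirical null of p-values from random
boundary pairs with the same one-bin separation constraint. Empirical
p-values use the add-one rule $(1 + \#\{\text{null} \ge \text{obs}\}) /
(n_{\text{null}} + 1)$, which can never return zero; the plain proportion
is available via `add_one = FALSE`. Per-changepoint results are reported
raw at $\alpha = 0.05$ (matching how such proportions are usually
summarized); users who need familywise control can adjust the emitted
p-values themselves. Counts features are summarized per 1 Mb tile within
each segment; continuous features use the track's native windows.

## The synthetic-data generator

`simulate_sample()` draws mutation positions from a uniform (or
piecewise-constant, rate-modulated) positional density over planted
segments that tile a synthetic genome, then draws each mutation's channel
from its segment's mixture $\sum_s \pi_s \mu_s$ and synthesizes the
context and ref/alt from the channel label. Kataegis clusters can be
injected with controlled size and spacing. The bundled
`synthetic_catalog()` builds up to six signatures with block supports and
a tunable `overlap` fraction, so pairwise cosine similarity — hence
identifiability — is controlled and tests remain self-contained; real
COSMIC-style files load through `read_signature_catalog()`.

The generator emulates the features the method actually consumes:
positional ordering, per-region channel composition, local hypermutation,
and independent feature tracks. It does *not* emulate replication-timing
covariation of mutation rate, strand asymmetries, clonal structure, or
sequencing noise — so passing tests demonstrate correctness of the
estimation and testing machinery under the stated model, not robustness
to every property of real tumor genomes. The piecewise density mode
exists precisely to check that rate changes alone, without composition
changes, do not produce changepoints.

Default study conditions used by the test-bench and the acceptance
script: 20 bins of 100 mutations (2,000 mutations on a 200 Mb
chromosome), a 4-signature catalog at `overlap = 0.15`, planted switches
with flanking-activity cosine distance about 0.36, bootstrap checks at
200 mutations per bin with an orthogonal 2-signature catalog, and
randomization-test calibration at 200 simulated samples with 500 (overlap)
or 200 (flank) null draws. These sizes were chosen as the smallest at
which the per-segment estimates are stable, and they keep the full bench
run in minutes on one core.

## A worked example

```{r example, eval = FALSE}
catalog <- synthetic_catalog(4, overlap = 0.15)
layout <- genome_layout("1", 2e8)
segs <- data.frame(chrom = "1", start = c(0, 1e8), end = c(1e8, 2e8))
act <- rbind(c(0.45, 0.30, 0.15, 0.10),
             c(0.15, 0.15, 0.30, 0.40))
cfg <- simulation_config(layout, catalog, segs, act,
                         n_mutations = 2000, seed = 42)
sim <- simulate_sample(cfg)

profile <- run_profile(sim$mutations, catalog, bin_size = 100,
                       mode = "genome")
profile$changepoints
report <- bootstrap_profile(sim$mutations, catalog, bin_size = 100,
                            mode = "genome", n_bootstraps = 5, seed = 1)
report$table
```

## Numerical choices and limitations

* EM tolerance `1e-6` on the log-likelihood; uniform start; no restarts
  (concavity); exact zeros permitted.
* Ties in the segmentation DP resolve to the earliest candidate, and ties
  between equally maximal recurrence windows to the leftmost — both for
  determinism.
* Internal interval coordinates are 0-based half-open; mutation positions
  are 1-based; BED is read natively and GFF converted on input.
* Chromosome labels are normalized by stripping a leading `chr`;
  non-canonical contigs are dropped with a warning.
* Cross-chromosome nearest-event distances are measured along the
  end-to-end chromosome concatenation — a reporting convention that can
  exceed any chromosome length, not a biological distance.
* A genome-wise changepoint falling exactly at a chromosome junction is
  reported on the right-hand chromosome and flagged `cross_chrom`.
* The segmentation cost refits every candidate segment from the uniform
  start rather than warm-starting from neighbors, keeping costs
  order-independent so the dynamic program is exact; this is the main
  runtime cost and the reason bin counts in the hundreds are comfortable
  while tens of thousands of bins are not.
* Recurrence region counts are guaranteed monotone in the threshold only
  when clusters are separated at the window scale; adjacent clusters can
  merge at lower thresholds.
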