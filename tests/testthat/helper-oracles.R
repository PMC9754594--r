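# Shared fixtures and independent oracles used across the test files.
# The oracles deliberately take the dumbest correct route (enumeration,
# brute-force scans, grid search) so they stay independent of the code
# paths they check.

tiny_layout <- function() genome_layout(c("1", "2"), c(2e8, 1.5e8))

# two-segment simulation on one chromosome with a planted activity switch
planted_switch_config <- function(seed, catalog, act_left, act_right,
                                  n_mutations = 2000, chrom_len = 2e8) {
  lay <- genome_layout("1", chrom_len)
  segs <- data.frame(chrom = "1", start = c(0, chrom_len / 2),
                     end = c(chrom_len / 2, chrom_len))
  simulation_config(lay, catalog, segs, rbind(act_left, act_right),
                    n_mutations = n_mutations, seed = seed)
}

# constant-activity (null) simulation on one chromosome
null_config <- function(seed, catalog, act, n_mutations = 2000,
                        chrom_len = 2e8) {
  lay <- genome_layout("1", chrom_len)
  segs <- data.frame(chrom = "1", start = 0, end = chrom_len)
  simulation_config(lay, catalog, segs, matrix(act, 1),
                    n_mutations = n_mutations, seed = seed)
}

# does the profile recover the planted truth at +/- k bins? Returns the
# per-sample recovery list from evaluate_recovery, with each detected
# boundary widened by k bins on each side.
recovery_at_bin_tolerance <- function(profile, truth, k = 1) {
  bins <- profile$series$bins
  B <- nrow(bins)
  cps <- profile$changepoints
  if (nrow(cps) == 0)
    return(evaluate_recovery(truth, cps))
  widened <- data.frame(
    chrom = cps$chrom,
    start = bins$pos_start[pmax(cps$boundary - k, 1)] - 1,
    end = bins$pos_end[pmin(cps$boundary + 1 + k, B)],
    stringsAsFactors = FALSE)
  evaluate_recovery(truth, widened)
}

# exhaustive optimal segmentation: enumerate every admissible boundary
# set (pairwise gaps >= 2) and minimize total cost + penalty per boundary
exhaustive_segmentation <- function(counts, catalog, penalty) {
  B <- nrow(counts)
  seg_cost <- function(i, j)
    -2 * em_fit(colSums(counts[i:j, , drop = FALSE]), catalog)$log_likelihood
  sets <- list(integer(0))
  if (B >= 2) {
    for (n in 1:ceiling((B - 1) / 2)) {
      cmb <- utils::combn(1:(B - 1), n, simplify = FALSE)
      cmb <- Filter(function(s) n == 1 || min(diff(s)) >= 2, cmb)
      sets <- c(sets, cmb)
    }
  }
  costs <- vapply(sets, function(s) {
    starts <- c(1, s + 1); ends <- c(s, B)
    sum(mapply(seg_cost, starts, ends)) + penalty * length(s)
  }, numeric(1))
  list(boundaries = sets[[which.min(costs)]], cost = min(costs))
}

# brute-force kataegis scan: test every (i, j) window, keep qualifying
# ones, merge index-overlapping windows
brute_kataegis <- function(pos, min_mutations = 6, max_mean_gap = 1000) {
  pos <- sort(pos)
  n <- length(pos)
  qual <- list()
  if (n >= min_mutations) {
    for (i in 1:(n - min_mutations + 1)) {
      for (j in (i + min_mutations - 1):n) {
        if ((pos[j] - pos[i]) / (j - i) <= max_mean_gap)
          qual[[length(qual) + 1]] <- c(i, j)
      }
    }
  }
  if (length(qual) == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_mutations = integer(0)))
  m <- do.call(rbind, qual)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  merged <- list(m[1, ])
  if (nrow(m) > 1) for (r in 2:nrow(m)) {
    cur <- merged[[length(merged)]]
    if (m[r, 1] <= cur[2])
      merged[[length(merged)]] <- c(cur[1], max(cur[2], m[r, 2]))
    else merged[[length(merged) + 1]] <- m[r, ]
  }
  do.call(rbind, lapply(merged, function(e)
    data.frame(start = pos[e[1]], end = pos[e[2]],
               n_mutations = e[2] - e[1] + 1L)))
}

# two-sided Fisher p for a 2x2 table by full enumeration of tables with
# the observed margins (sum of hypergeometric probabilities <= observed)
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) stats::dhyper(a, r1, r2, c1), numeric(1))
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# brute-force sliding-window recurrence scan: every window, distinct
# samples, runs merged, peak window reported
brute_recurrent_regions <- function(ranges, layout, window, step, threshold) {
  out <- list()
  for (ci in seq_len(nrow(layout))) {
    ch <- layout$chrom[ci]; len <- layout$length[ci]
    rr <- ranges[ranges$chrom == ch, , drop = FALSE]
    if (nrow(rr) == 0) next
    starts <- seq(0, max(0, len - 1), by = step)
    counts <- vapply(starts, function(s) {
      e <- min(s + window, len)
      length(unique(rr$sample[rr$start < e & rr$end > s]))
    }, numeric(1))
    ok <- which(counts >= threshold)
    if (length(ok) == 0) next
    grp <- cumsum(c(1, diff(ok) > 1))
    for (g in split(ok, grp)) {
      peak <- g[which.max(counts[g])]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = starts[g[1]],
        end = min(starts[g[length(g)]] + window, len),
        peak_start = starts[peak], n_samples = counts[peak],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), peak_start = numeric(0),
                      n_samples = numeric(0)))
  do.call(rbind, out)
}

# build a signature_profile shell around a bin series with the given
# changepoint boundaries (for randomization-test simulations where the
# boundaries are planted rather than detected)
profile_with_boundaries <- function(series, boundaries) {
  cps <- if (length(boundaries) == 0) {
    data.frame(boundary = integer(0), chrom = character(0),
               start = numeric(0), end = numeric(0),
               cross_chrom = logical(0), magnitude = numeric(0),
               support = numeric(0))
  } else {
    iv <- do.call(rbind, lapply(sort(boundaries), function(b)
      sigseg:::boundary_interval(series, b)))
    data.frame(boundary = sort(boundaries), iv, magnitude = NA_real_,
               support = NA_real_)
  }
  structure(list(series = series, segments = NULL, activity = NULL,
                 changepoints = cps, mode = series$mode,
                 bin_size = series$bin_size, sample_id = series$sample_id,
                 penalty_scale = 1),
            class = "signature_profile")
}
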