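# resample channel counts within each bin (multinomial with the same bin
# size); bin boundaries and spans are held fixed
resample_counts <- function(series) {
  counts <- series$counts
  for (b in seq_len(nrow(counts))) {
    n <- sum(counts[b, ])
    if (n > 0)
      counts[b, ] <- as.integer(stats::rmultinom(1, n, counts[b, ] / n))
  }
  out <- series
  out$counts <- counts
  out
}

# per-replicate seed derivation from a single user seed (kept < 2^31)
derive_seed <- function(seed, r) (as.numeric(seed) * 7919 + r * 104729) %% 2147483647

#' Bootstrap changepoint placement confidence
#'
#' Quantifies confidence in the changepoints of a profile by within-bin
#' resampling: bin boundaries are held fixed, the mutations within each bin
#' are resampled with replacement to the same bin size, and the full
#' segmentation is re-run. A baseline changepoint's support is the fraction
#' of bootstrap runs that place a changepoint within one bin of its
#' boundary; changepoints found in more than one bootstrap sample are
#' flagged high-confidence.
#'
#' @param mutations mutation data frame.
#' @param catalog a [signature_catalog()].
#' @param bin_size mutations per bin.
#' @param mode "chromosome" or "genome".
#' @param n_bootstraps number of bootstrap replicates (default 5).
#' @param seed integer seed; every replicate derives its own stream from it.
#' @param penalty_scale multiplier on the BIC penalty.
#' @return A `bootstrap_report`: list with the baseline `profile` (its
#'   `changepoints$support` filled in), `n_bootstraps`, a `table` data
#'   frame (boundary, interval, magnitude, `n_found`, `support`,
#'   `high_confidence`), `boot_locations` (per baseline changepoint, the
#'   genomic midpoints of matching replicate boundaries), and
#'   `replicate_boundaries`.
#' @export
bootstrap_profile <- function(mutations, catalog, bin_size = 100,
                              mode = c("chromosome", "genome"),
                              n_bootstraps = 5, seed = 1,
                              penalty_scale = 1) {
  mode <- match.arg(mode)
  baseline <- run_profile(mutations, catalog, bin_size = bin_size,
                          mode = mode, penalty_scale = penalty_scale)
  bootstrap_from_profile(baseline, catalog, n_bootstraps, seed)
}

# bootstrap machinery on an existing baseline profile (shared with the
# resampling-robustness protocol)
bootstrap_from_profile <- function(baseline, catalog, n_bootstraps, seed) {
  rep_bnd <- vector("list", n_bootstraps)
  rep_mid <- vector("list", n_bootstraps)
  for (r in seq_len(n_bootstraps)) {
    set.seed(derive_seed(seed, r))
    rs <- resample_counts(baseline$series)
    prof <- profile_from_series(rs, catalog, baseline$penalty_scale)
    rep_bnd[[r]] <- prof$changepoints$boundary
    rep_mid[[r]] <- (prof$changepoints$start + prof$changepoints$end) / 2
  }
  cps <- baseline$changepoints
  n_cp <- nrow(cps)
  n_found <- integer(n_cp)
  boot_loc <- vector("list", n_cp)
  for (k in seq_len(n_cp)) {
    hits <- vapply(rep_bnd, function(b)
      any(abs(b - cps$boundary[k]) <= 1), logical(1))
    n_found[k] <- sum(hits)
    boot_loc[[k]] <- unlist(lapply(which(hits), function(r) {
      j <- which(abs(rep_bnd[[r]] - cps$boundary[k]) <= 1)
      rep_mid[[r]][j]
    }))
  }
  support <- if (n_cp > 0) n_found / n_bootstraps else numeric(0)
  baseline$changepoints$support <- support
  tab <- cbind(cps[, c("boundary", "chrom", "start", "end", "magnitude")],
               n_found = n_found, support = support,
               high_confidence = n_found > 1)
  structure(list(profile = baseline, n_bootstraps = n_bootstraps,
                 table = tab, boot_locations = boot_loc,
                 replicate_boundaries = rep_bnd, seed = seed),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat("bootstrap_report:", x$n_bootstraps, "replicates,",
      nrow(x$table), "baseline changepoint(s)\n")
  invisible(x)
}

#' Cohort-level changepoint robustness through resampling
#'
#' Rebuilds each genome's activity profile from within-bin resamples
#' (holding bin boundaries fixed) and asks, at the cohort level, whether
#' the recurrent changepoint regions of the original profiles are
#' recovered as recurrent among the resampled profiles, and, per sample,
#' what fraction of its resampled profiles recover each baseline
#' changepoint (within one bin).
#'
#' @param cohort named list of mutation data frames (one per sample).
#' @param catalog a [signature_catalog()].
#' @param layout a [genome_layout()].
#' @param bin_size mutations per bin.
#' @param mode "chromosome" or "genome".
#' @param n_resamples resampled profiles per genome (default 20).
#' @param threshold samples required for a recurrent region (default 7).
#' @param window,step sliding-window size and step in bp for recurrence.
#' @param seed integer seed.
#' @return List with `tissue_table` (one row per baseline recurrent
#'   region: `n_samples_original`, `n_samples_resampled`, `recovered`) and
#'   `sample_table` (per sample x baseline changepoint: fraction of
#'   resampled profiles recovering it). A cohort without recurrent
#'   changepoints yields empty tables with a notice.
#' @export
resample_robustness <- function(cohort, catalog, layout, bin_size = 100,
                                mode = c("chromosome", "genome"),
                                n_resamples = 20, threshold = 7,
                                window = 1e6, step = 5e5, seed = 1) {
  mode <- match.arg(mode)
  ids <- names(cohort)
  if (is.null(ids)) ids <- paste0("sample", seq_along(cohort))
  profiles <- lapply(seq_along(cohort), function(i)
    run_profile(cohort[[i]], catalog, bin_size = bin_size, mode = mode))
  names(profiles) <- ids

  ranges_orig <- cohort_changepoint_ranges(profiles, layout)
  regions <- find_recurrent_regions(ranges_orig, layout, window = window,
                                    step = step, threshold = threshold)
  if (nrow(regions) == 0) {
    message("no recurrent changepoint regions in the original profiles")
    return(list(tissue_table = regions,
                sample_table = data.frame(),
                regions_original = regions))
  }

  resampled <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    resampled[[i]] <- vector("list", n_resamples)
    for (r in seq_len(n_resamples)) {
      set.seed(derive_seed(seed + i * 131, r))
      rs <- resample_counts(profiles[[i]]$series)
      resampled[[i]][[r]] <- profile_from_series(rs, catalog,
                                                 profiles[[i]]$penalty_scale)
    }
  }

  # tissue-level: distinct samples with any resampled-profile changepoint
  # range overlapping each baseline recurrent region
  res_ranges <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    rr <- lapply(resampled[[i]], function(p)
      cohort_changepoint_ranges(stats::setNames(list(p), ids[i]), layout))
    do.call(rbind, rr)
  }))
  n_res <- vapply(seq_len(nrow(regions)), function(k) {
    if (is.null(res_ranges) || nrow(res_ranges) == 0) return(0L)
    hit <- res_ranges$chrom == regions$chrom[k] &
      res_ranges$start < regions$end[k] & res_ranges$end > regions$start[k]
    length(unique(res_ranges$sample[hit]))
  }, integer(1))
  tissue <- cbind(regions[, c("chrom", "start", "end", "n_samples")],
                  n_samples_resampled = n_res,
                  recovered = n_res >= threshold)
  names(tissue)[names(tissue) == "n_samples"] <- "n_samples_original"

  # sample-level: fraction of resampled profiles recovering each baseline
  # changepoint within one bin
  sample_rows <- list()
  for (i in seq_along(cohort)) {
    cps <- profiles[[i]]$changepoints
    if (nrow(cps) == 0) next
    for (k in seq_len(nrow(cps))) {
      hits <- vapply(resampled[[i]], function(p)
        any(abs(p$changepoints$boundary - cps$boundary[k]) <= 1), logical(1))
      sample_rows[[length(sample_rows) + 1]] <- data.frame(
        sample = ids[i], boundary = cps$boundary[k], chrom = cps$chrom[k],
        start = cps$start[k], end = cps$end[k],
        fraction_recovered = mean(hits), stringsAsFactors = FALSE)
    }
  }
  list(tissue_table = tissue,
       sample_table = if (length(sample_rows)) do.call(rbind, sample_rows)
                      else data.frame(),
       regions_original = regions)
}

# per-sample changepoint ranges for a list of profiles (bin-span fallback;
# see changepoint_range for the KDE form used when bootstrap locations
# are available)
cohort_changepoint_ranges <- function(profiles, layout) {
  ids <- names(profiles)
  out <- lapply(seq_along(profiles), function(i) {
    cps <- profiles[[i]]$changepoints
    if (nrow(cps) == 0) return(NULL)
    data.frame(sample = ids[i], chrom = cps$chrom,
               start = cps$start, end = cps$end, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    data.frame(sample = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), stringsAsFactors = FALSE)
  else out
}
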