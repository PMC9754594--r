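# pooled channel counts of bins i..j via a cumulative matrix
pooled_counts <- function(cum, i, j) cum[j + 1, ] - cum[i, ]

#' Cost and activity of a candidate segment
#'
#' Pools the channel counts of bins `i..j`, fits activities by [em_fit()],
#' and returns `cost = -2 * log_likelihood` together with the fitted
#' activity vector. This is the segment cost minimized by the optimal
#' segmentation; it is superadditive (pooling never beats fitting parts
#' separately), which is what makes PELT pruning exact.
#'
#' @param bins a `bin_series`.
#' @param i,j first and last bin index (1-based, inclusive).
#' @param catalog a [signature_catalog()].
#' @return List with `cost` and `activity`.
#' @export
segment_cost <- function(bins, i, j, catalog) {
  stopifnot(inherits(bins, "bin_series"),
            i >= 1, i <= j, j <= nrow(bins$bins))
  counts <- colSums(bins$counts[i:j, , drop = FALSE])
  fit <- em_fit(counts, catalog)
  list(cost = -2 * fit$log_likelihood, activity = fit$activity)
}

#' Default BIC changepoint penalty
#'
#' Each additional segment adds S - 1 free mixture parameters, so on the
#' `-2 log L` cost scale the BIC charge per changepoint is
#' `(S - 1) * log(N)` with N the total number of mutations in the series
#' being segmented. With a single signature there is no free mixture
#' parameter and no changepoint is identifiable: the penalty is +Inf with
#' a warning.
#'
#' @param bins a `bin_series`.
#' @param catalog a [signature_catalog()].
#' @return Scalar penalty.
#' @export
default_penalty <- function(bins, catalog) {
  stopifnot(inherits(bins, "bin_series"), inherits(catalog, "signature_catalog"))
  S <- nrow(catalog)
  if (S == 1) {
    warning("single-signature catalog: no changepoint is identifiable")
    return(Inf)
  }
  (S - 1) * log(sum(bins$counts))
}

# PELT dynamic program over a B x 96 count matrix.
# Boundary b (1..B-1) means "between bins b and b+1"; boundaries must
# differ by >= 2 (no changepoints at adjacent bins); every segment has
# >= 1 bin. Candidate s = last boundary so far (0 = none). Pruning drops
# candidates dominated at the current endpoint, which is exact because
# segment costs are superadditive.
pelt_counts <- function(counts, catalog, penalty) {
  B <- nrow(counts)
  cum <- rbind(0, apply(counts, 2, cumsum))
  if (B == 1) cum <- rbind(0, matrix(counts, 1))
  cache <- new.env(parent = emptyenv())
  cost_f <- function(i, j) {
    key <- paste0(i, ".", j)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    fit <- em_fit(pooled_counts(cum, i, j), catalog)
    val <- list(cost = -2 * fit$log_likelihood, activity = fit$activity)
    cache[[key]] <- val
    val
  }
  if (B == 1 || !is.finite(penalty)) {
    fit <- cost_f(1, B)
    return(list(boundaries = integer(0), segments = cbind(1L, B),
                activity = matrix(fit$activity, 1,
                                  dimnames = list(NULL, rownames(catalog))),
                seg_cost = fit$cost, total_cost = fit$cost, cost_f = cost_f))
  }
  G <- rep(Inf, B)       # G[b+1]: best penalized cost of bins 1..b with a
  G[1] <- 0              # boundary at b (b = 0: virtual start, no penalty)
  prev <- integer(B)
  cand <- 0L             # last-boundary candidates (0 = none yet)
  mark <- Inf            # step at which a candidate became dominated
  for (b in seq_len(B - 1)) {
    if (b - 2 >= 1) {                         # newly eligible (gap >= 2)
      cand <- c(cand, b - 2L)
      mark <- c(mark, Inf)
    }
    # a candidate dominated at step m is still admissible at step m + 1
    # (its dominating comparator, a boundary at m, is not: adjacency),
    # so removal is delayed by one step
    keep <- mark >= b - 1
    cand <- cand[keep]; mark <- mark[keep]
    vals <- vapply(cand, function(s) G[s + 1] + cost_f(s + 1, b)$cost,
                   numeric(1))
    G[b + 1] <- penalty + min(vals)
    prev[b + 1] <- cand[which.min(vals)]
    mark[is.infinite(mark) & vals > G[b + 1]] <- b  # PELT pruning
  }
  final_cand <- unique(c(cand[mark >= B - 1],
                         if (B - 2 >= 1) B - 2L, B - 1L))
  fvals <- vapply(final_cand,
                  function(s) G[s + 1] + cost_f(s + 1, B)$cost, numeric(1))
  last <- final_cand[which.min(fvals)]
  total <- min(fvals)
  bnd <- integer(0)
  s <- last
  while (s > 0) {
    bnd <- c(s, bnd)
    s <- prev[s + 1]
  }
  starts <- c(1L, bnd + 1L)
  ends <- c(bnd, B)
  fits <- lapply(seq_along(starts), function(k) cost_f(starts[k], ends[k]))
  list(boundaries = bnd,
       segments = cbind(starts, ends),
       activity = do.call(rbind, lapply(fits, `[[`, "activity")),
       seg_cost = vapply(fits, `[[`, numeric(1), "cost"),
       total_cost = total, cost_f = cost_f)
}

#' Optimal segmentation of a bin series
#'
#' Finds the segmentation of the series minimizing the sum of segment costs
#' (see [segment_cost()]) plus `penalty` per changepoint, subject to a
#' minimum segment length of one bin and no changepoints at adjacent bins,
#' using the PELT algorithm. The pruning is exact, so the result equals
#' exhaustive dynamic programming over all admissible changepoint sets.
#'
#' @param bins a `bin_series`.
#' @param catalog a [signature_catalog()].
#' @param penalty per-changepoint penalty on the `-2 log L` scale; defaults
#'   to [default_penalty()].
#' @return A `segmentation_result`: list with `segments` (data frame),
#'   `activity` (segments x signatures matrix), `changepoints` (data frame
#'   with `boundary` — between bins `boundary` and `boundary + 1` —,
#'   genomic interval in 0-based half-open coordinates, and cosine-distance
#'   `magnitude`; `support` is NA until filled by [bootstrap_profile()]),
#'   `total_penalized_cost` and `penalty_used`.
#' @export
pelt_segment <- function(bins, catalog, penalty = NULL) {
  stopifnot(inherits(bins, "bin_series"), inherits(catalog, "signature_catalog"))
  if (is.null(penalty)) penalty <- default_penalty(bins, catalog)
  res <- pelt_counts(bins$counts, catalog, penalty)
  build_segmentation(bins, catalog, res, penalty)
}

# assemble the user-facing result from a pelt_counts() fit
build_segmentation <- function(bins, catalog, res, penalty) {
  bdf <- bins$bins
  segs <- data.frame(
    segment = seq_len(nrow(res$segments)),
    start_bin = res$segments[, 1],
    end_bin = res$segments[, 2],
    chrom_start = bdf$chrom_start[res$segments[, 1]],
    pos_start = bdf$pos_start[res$segments[, 1]],
    chrom_end = bdf$chrom_end[res$segments[, 2]],
    pos_end = bdf$pos_end[res$segments[, 2]],
    n_mutations = vapply(seq_len(nrow(res$segments)), function(k)
      sum(bdf$n[res$segments[k, 1]:res$segments[k, 2]]), numeric(1)),
    log_likelihood = -res$seg_cost / 2,
    stringsAsFactors = FALSE)
  cps <- if (length(res$boundaries) == 0) {
    data.frame(boundary = integer(0), chrom = character(0),
               start = numeric(0), end = numeric(0),
               cross_chrom = logical(0), magnitude = numeric(0),
               support = numeric(0), stringsAsFactors = FALSE)
  } else {
    iv <- do.call(rbind, lapply(res$boundaries,
                                function(b) boundary_interval(bins, b)))
    mag <- vapply(seq_along(res$boundaries), function(k)
      changepoint_magnitude(res$activity[k, ], res$activity[k + 1, ]),
      numeric(1))
    data.frame(boundary = res$boundaries, iv, magnitude = mag,
               support = NA_real_, stringsAsFactors = FALSE)
  }
  structure(list(segments = segs, activity = res$activity,
                 changepoints = cps,
                 total_penalized_cost = res$total_cost,
                 penalty_used = penalty,
                 sample_id = bins$sample_id, mode = bins$mode,
                 bin_size = bins$bin_size),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("segmentation_result: ", nrow(x$segments), " segment(s), ",
      nrow(x$changepoints), " changepoint(s), penalty ",
      signif(x$penalty_used, 4), "\n", sep = "")
  invisible(x)
}

# subset a bin_series to a run of bins, renumbering from 1
subset_series <- function(series, idx) {
  mut_keep <- series$mutations
  # recompute bin membership from spans is fragile; carry bin index instead
  structure(list(bins = transform(series$bins[idx, , drop = FALSE],
                                  bin = seq_along(idx)),
                 counts = series$counts[idx, , drop = FALSE],
                 mode = series$mode, bin_size = series$bin_size,
                 sample_id = series$sample_id,
                 mutations = series$mutations,
                 chrom_order = series$chrom_order),
            class = "bin_series")
}

#' Construct a regional signature activity profile
#'
#' End-to-end driver: bins the mutations, segments by PELT, and reports
#' per-segment activities and changepoints. In chromosome-wise mode each
#' chromosome is binned and segmented independently (with its own BIC
#' penalty) and the per-chromosome results are concatenated; chromosome
#' boundaries are never themselves counted as changepoints. In genome-wise
#' mode the canonical end-to-end concatenation is segmented as one series.
#'
#' @param mutations mutation data frame (see [read_mutations()]).
#' @param catalog a [signature_catalog()] of the signatures to fit.
#' @param bin_size mutations per bin (default 100).
#' @param mode "chromosome" or "genome".
#' @param penalty_scale multiplier on the BIC penalty (default 1).
#' @param exclude_xy drop mutations on X and Y first (e.g. to match
#'   autosome-only copy-number calls).
#' @return A `signature_profile`: list with the `series` (full
#'   `bin_series`), `segments`, `activity`, `changepoints` (global bin
#'   indexing) and `penalty_scale`.
#' @export
run_profile <- function(mutations, catalog, bin_size = 100,
                        mode = c("chromosome", "genome"),
                        penalty_scale = 1, exclude_xy = FALSE) {
  mode <- match.arg(mode)
  if (exclude_xy)
    mutations <- mutations[!mutations$chrom %in% c("X", "Y"), , drop = FALSE]
  series <- make_bins(mutations, bin_size = bin_size,
                      mode = if (mode == "genome") "genome" else "chromosome")
  profile_from_series(series, catalog, penalty_scale)
}

# segmentation driver on an existing bin_series (shared with bootstrap)
profile_from_series <- function(series, catalog, penalty_scale = 1) {
  if (series$mode == "genome") {
    pen <- default_penalty(series, catalog) * penalty_scale
    seg <- pelt_segment(series, catalog, penalty = pen)
    segments <- seg$segments
    activity <- seg$activity
    changepoints <- seg$changepoints
  } else {
    chroms <- unique(series$bins$chrom_start)
    seg_list <- list(); cp_list <- list(); act_list <- list()
    offset <- 0L
    for (ch in chroms) {
      idx <- which(series$bins$chrom_start == ch)
      sub <- subset_series(series, idx)
      pen <- default_penalty(sub, catalog) * penalty_scale
      seg <- pelt_segment(sub, catalog, penalty = pen)
      seg$segments$start_bin <- seg$segments$start_bin + offset
      seg$segments$end_bin <- seg$segments$end_bin + offset
      if (nrow(seg$changepoints) > 0)
        seg$changepoints$boundary <- seg$changepoints$boundary + offset
      seg_list[[ch]] <- seg$segments
      cp_list[[ch]] <- seg$changepoints
      act_list[[ch]] <- seg$activity
      offset <- offset + length(idx)
    }
    segments <- do.call(rbind, seg_list)
    segments$segment <- seq_len(nrow(segments))
    rownames(segments) <- NULL
    changepoints <- do.call(rbind, cp_list)
    rownames(changepoints) <- NULL
    activity <- do.call(rbind, act_list)
  }
  structure(list(series = series, segments = segments, activity = activity,
                 changepoints = changepoints, catalog_names = rownames(catalog),
                 mode = series$mode, bin_size = series$bin_size,
                 sample_id = series$sample_id, penalty_scale = penalty_scale),
            class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  cat("signature_profile (", x$mode, "-wise): ", nrow(x$series$bins),
      " bins, ", nrow(x$segments), " segment(s), ", nrow(x$changepoints),
      " changepoint(s)\n", sep = "")
  invisible(x)
}

#' Write profile activity and changepoint tables
#'
#' Emits `<prefix>_activity.tsv` (one row per segment with one column per
#' signature) and `<prefix>_changepoints.tsv` (boundary, 0-based half-open
#' genomic interval, magnitude, support).
#'
#' @param profile a `signature_profile`.
#' @param prefix output path prefix.
#' @return Invisibly, the two paths.
#' @export
write_profile <- function(profile, prefix) {
  act <- cbind(profile$segments,
               as.data.frame(profile$activity, check.names = FALSE))
  p1 <- paste0(prefix, "_activity.tsv")
  utils::write.table(act, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- paste0(prefix, "_changepoints.tsv")
  utils::write.table(profile$changepoints, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
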