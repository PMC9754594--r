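#' Location range of a changepoint from its bootstrap locations
#'
#' Fits a Gaussian kernel density estimate (Silverman's rule-of-thumb
#' bandwidth, as in [stats::density()]'s default) over the vector of
#' genomic locations attributed to a changepoint — its boundary midpoint
#' across bootstrap replicates, optionally augmented with flanking-bin
#' mutation positions — and returns the interval mean +/- one standard
#' deviation of that density (the sample spread inflated by the
#' bandwidth), clipped to the chromosome. With a single location, or zero
#' spread, the range degrades to the changepoint's bin span.
#'
#' @param locations numeric vector of genomic positions (bp), all on one
#'   chromosome.
#' @param chrom chromosome label of the changepoint.
#' @param fallback_start,fallback_end the flanking-bin span (0-based
#'   half-open) used when the KDE is degenerate.
#' @param layout optional [genome_layout()] used to clip to chromosome
#'   bounds.
#' @return data frame with `chrom`, `start`, `end`.
#' @export
changepoint_range <- function(locations, chrom, fallback_start,
                              fallback_end, layout = NULL) {
  locations <- as.numeric(locations)
  if (length(locations) == 0)
    return(data.frame(chrom = chrom, start = fallback_start,
                      end = fallback_end, stringsAsFactors = FALSE))
  if (length(locations) == 1 || stats::sd(locations) == 0)
    return(data.frame(chrom = chrom, start = fallback_start,
                      end = fallback_end, stringsAsFactors = FALSE))
  bw <- stats::bw.nrd0(locations)
  m <- mean(locations)
  # sd of the KDE as a density: population variance plus squared bandwidth
  s <- sqrt(mean((locations - m)^2) + bw^2)
  lo <- m - s
  hi <- m + s
  if (!is.null(layout)) {
    len <- layout$length[match(chrom, layout$chrom)]
    lo <- max(0, lo)
    hi <- min(len, hi)
  }
  data.frame(chrom = chrom, start = lo, end = hi, stringsAsFactors = FALSE)
}

#' Changepoint ranges for a bootstrapped profile
#'
#' Applies [changepoint_range()] to every baseline changepoint of a
#' [bootstrap_profile()] report, using the replicate boundary midpoints as
#' the location vector and the flanking-bin span as the degenerate
#' fallback.
#'
#' @param report a `bootstrap_report`.
#' @param layout optional [genome_layout()] for clipping.
#' @return data frame with `sample`, `chrom`, `start`, `end`, `boundary`.
#' @export
profile_changepoint_ranges <- function(report, layout = NULL) {
  cps <- report$profile$changepoints
  if (nrow(cps) == 0)
    return(data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      boundary = integer(0), stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(cps)), function(k) {
    loc <- c(report$boot_locations[[k]], (cps$start[k] + cps$end[k]) / 2)
    r <- changepoint_range(loc, cps$chrom[k], cps$start[k], cps$end[k],
                           layout)
    cbind(sample = report$profile$sample_id, r, boundary = cps$boundary[k])
  })
  do.call(rbind, out)
}

#' Find recurrent changepoint regions across a cohort
#'
#' Slides windows of `window` bp at `step` bp across each chromosome and
#' counts how many distinct samples have a changepoint range overlapping
#' each window. Maximal runs of windows reaching `threshold` samples are
#' merged into regions; each region is centered at the window with the
#' maximum count (leftmost on ties). When per-changepoint activity
#' differences are supplied, each region also reports the mean activity
#' change across contributing changepoints and the signatures that
#' decrease and increase the most.
#'
#' @param ranges data frame of changepoint ranges with columns `sample`,
#'   `chrom`, `start`, `end` (0-based half-open), e.g. from
#'   [profile_changepoint_ranges()].
#' @param layout a [genome_layout()].
#' @param window sliding-window width in bp (default 1 Mb).
#' @param step window step in bp (default 0.5 Mb).
#' @param threshold distinct samples required (default 7).
#' @param delta optional numeric matrix (rows aligned with `ranges`) of
#'   per-signature activity differences (right minus left) at each
#'   changepoint.
#' @return data frame of regions: `chrom`, `start`, `end` (merged run of
#'   qualifying windows), `peak_start`, `peak_end` (maximal window),
#'   `n_samples`, and when `delta` is given `top_decrease`/`top_increase`;
#'   the mean activity-change matrix is attached as attribute
#'   `mean_delta`.
#' @export
find_recurrent_regions <- function(ranges, layout, window = 1e6,
                                   step = 5e5, threshold = 7,
                                   delta = NULL) {
  if (window <= 0) stop("window_size must be positive")
  if (step <= 0) stop("step must be positive")
  regions <- list()
  deltas <- list()
  for (ci in seq_len(nrow(layout))) {
    ch <- layout$chrom[ci]
    len <- layout$length[ci]
    rr <- which(ranges$chrom == ch)
    if (length(rr) == 0) next
    starts <- seq(0, max(0, len - 1), by = step)
    ends <- pmin(starts + window, len)
    # distinct samples overlapping each window
    counts <- integer(length(starts))
    for (w in seq_along(starts)) {
      hit <- ranges$start[rr] < ends[w] & ranges$end[rr] > starts[w]
      counts[w] <- length(unique(ranges$sample[rr][hit]))
    }
    ok <- counts >= threshold
    if (!any(ok)) next
    # maximal runs of qualifying windows
    run_id <- cumsum(c(1, diff(which(ok)) > 1))
    for (g in split(which(ok), run_id)) {
      peak <- g[which.max(counts[g])]
      contrib <- rr[ranges$start[rr] < ends[peak] &
                      ranges$end[rr] > starts[peak]]
      row <- data.frame(chrom = ch, start = starts[g[1]],
                        end = ends[g[length(g)]],
                        peak_start = starts[peak], peak_end = ends[peak],
                        n_samples = counts[peak], stringsAsFactors = FALSE)
      if (!is.null(delta)) {
        md <- colMeans(delta[contrib, , drop = FALSE])
        row$top_decrease <- names(md)[which.min(md)]
        row$top_increase <- names(md)[which.max(md)]
        deltas[[length(regions) + 1]] <- md
      }
      regions[[length(regions) + 1]] <- row
    }
  }
  if (length(regions) == 0) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), peak_start = numeric(0),
                      peak_end = numeric(0), n_samples = integer(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  if (!is.null(delta))
    attr(out, "mean_delta") <- do.call(rbind, deltas)
  out
}
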