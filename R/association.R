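# boundaries of a series that are admissible changepoint locations:
# 1..B-1, excluding chromosome junctions (a junction is not a changepoint)
admissible_boundaries <- function(series) {
  bdf <- series$bins
  B <- nrow(bdf)
  if (B < 2) return(integer(0))
  b <- seq_len(B - 1)
  b[bdf$chrom_end[b] == bdf$chrom_start[b + 1]]
}

# draw one admissible changepoint set: n boundaries, without replacement,
# pairwise gaps >= 2, uniform over admissible sets. Uses the bijection
# between gap-constrained k-subsets of 1..m and plain k-subsets of
# 1..m-k+1; draws containing an inadmissible boundary (a chromosome
# junction) are rejected, which preserves uniformity.
sample_boundary_set <- function(n, admissible) {
  if (n > ceiling(length(admissible) / 2))
    stop("more changepoints than admissible non-adjacent boundaries")
  if (n == 0) return(integer(0))
  m <- max(admissible)
  if (m - n + 1 < n)
    stop("more changepoints than admissible non-adjacent boundaries")
  for (i in 1:100000) {
    s <- sort(sample.int(m - n + 1, n)) + 0:(n - 1)
    if (all(s %in% admissible)) return(s)
  }
  stop("could not draw a non-adjacent boundary set")
}

# does each interval (chrom/start/end rows) overlap any feature interval?
overlaps_feature <- function(iv, feature) {
  vapply(seq_len(nrow(iv)), function(i) {
    any(feature$chrom == iv$chrom[i] &
          feature$start < iv$end[i] & feature$end > iv$start[i])
  }, logical(1))
}

#' Randomization test of changepoint-feature overlap
#'
#' Tests whether the proportion of a sample's changepoints overlapping a
#' discrete genomic feature (CNAs, kataegis events, TAD boundaries) is
#' higher than expected at random. A changepoint overlaps the feature when
#' any part of its region overlaps any part of a feature interval. The
#' null distribution is built from `n_null` random changepoint sets of the
#' same cardinality, drawn uniformly from the profile's admissible bin
#' boundaries (without replacement, no adjacent boundaries). The p-value
#' uses the add-one rule `(1 + #{null >= observed}) / (n_null + 1)`, which
#' never returns exactly zero; `add_one = FALSE` recovers the plain
#' proportion.
#'
#' @param profile a `signature_profile` with at least one changepoint.
#' @param feature feature data frame (`chrom`, `start`, `end`), non-empty.
#' @param n_null number of null sets (default 10000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @param add_one use the add-one p-value correction.
#' @param feature_name label carried into the result.
#' @return List of class `overlap_test`: `sample_id`, `feature`,
#'   `observed_p`, `null_p` (vector of null proportions), `p_value`,
#'   `significant`, `n_null`, `alpha`.
#' @export
overlap_test <- function(profile, feature, n_null = 10000, alpha = 0.05,
                         seed = 1, add_one = TRUE, feature_name = "feature") {
  stopifnot(inherits(profile, "signature_profile"))
  cps <- profile$changepoints
  if (nrow(cps) == 0) stop("profile has no changepoints to test")
  if (nrow(feature) == 0) stop("empty feature track")
  obs <- mean(overlaps_feature(cps, feature))
  adm <- admissible_boundaries(profile$series)
  # overlap status is fixed per boundary: precompute once
  iv <- do.call(rbind, lapply(adm, function(b)
    boundary_interval(profile$series, b)))
  o <- overlaps_feature(iv, feature)
  names(o) <- adm
  set.seed(seed)
  null_p <- vapply(seq_len(n_null), function(i)
    mean(o[as.character(sample_boundary_set(nrow(cps), adm))]), numeric(1))
  p_value <- if (add_one) (1 + sum(null_p >= obs)) / (n_null + 1)
             else mean(null_p >= obs)
  structure(list(sample_id = profile$sample_id, feature = feature_name,
                 observed_p = obs, null_p = null_p, p_value = p_value,
                 significant = p_value < alpha, n_null = n_null,
                 alpha = alpha),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("overlap_test [", x$feature, "]: observed p = ", signif(x$observed_p, 3),
      ", p-value = ", signif(x$p_value, 3),
      if (x$significant) " (significant)" else "", "\n", sep = "")
  invisible(x)
}

#' Changepoint-containing and flank segments
#'
#' Given the midpoint of a changepoint region and the midpoint of its
#' nearest neighbor in one direction (the next changepoint, or the
#' chromosome boundary when none exists), let m be the midpoint between
#' the two; the changepoint-containing segment is centered at the
#' changepoint with width equal to the distance from the changepoint to m,
#' and the flank segment is centered at the neighbor with the same width.
#' Both are clipped to the chromosome (clipping recorded in attribute
#' `clipped`).
#'
#' @param mid_c midpoint of the changepoint region (bp).
#' @param mid_neighbor midpoint of the neighboring anchor (bp).
#' @param chrom_length chromosome length for clipping (default `Inf`).
#' @return List with `changepoint = c(start, end)`, `flank = c(start,
#'   end)` and `width`.
#' @export
flank_segments <- function(mid_c, mid_neighbor, chrom_length = Inf) {
  if (mid_c == mid_neighbor) stop("coincident changepoint and neighbor")
  w <- abs(mid_neighbor - mid_c) / 2
  cp <- c(mid_c - w / 2, mid_c + w / 2)
  fl <- c(mid_neighbor - w / 2, mid_neighbor + w / 2)
  clip <- function(x) pmin(pmax(x, 0), chrom_length)
  out <- list(changepoint = clip(cp), flank = clip(fl), width = w)
  attr(out, "clipped") <- !identical(out$changepoint, cp) ||
    !identical(out$flank, fl)
  out
}

# feature sample within a genomic segment [s, e) on chrom:
#  continuous -> the values of overlapping feature windows
#  counts     -> per-tile event counts (tiles of `window` bp)
segment_feature_sample <- function(feature, chrom, s, e, kind, window) {
  if (kind == "continuous") {
    f <- feature$chrom == chrom & feature$start < e & feature$end > s
    feature$value[f]
  } else {
    if (e - s < window) tile_starts <- s
    else tile_starts <- seq(s, e - window, by = window)
    tile_ends <- pmin(tile_starts + window, e)
    f <- which(feature$chrom == chrom & feature$start < e & feature$end > s)
    vapply(seq_along(tile_starts), function(t)
      sum(feature$start[f] < tile_ends[t] & feature$end[f] > tile_starts[t]),
      numeric(1))
  }
}

# inner two-sample test: KS for continuous values, Fisher on
# [total events, zero-event windows] x [changepoint, flank] for counts
inner_flank_test <- function(x_cp, x_fl, kind) {
  if (length(x_cp) == 0 || length(x_fl) == 0) return(NA_real_)
  if (kind == "continuous") {
    suppressWarnings(stats::ks.test(x_cp, x_fl)$p.value)
  } else {
    tab <- matrix(c(sum(x_cp), sum(x_cp == 0), sum(x_fl), sum(x_fl == 0)), 2)
    if (all(tab[1, ] == 0)) return(1)
    stats::fisher.test(tab)$p.value
  }
}

#' Randomization test of feature distributions around changepoints
#'
#' For each changepoint, compares the distribution of a genomic feature
#' between the changepoint-containing segment and an equally sized flank
#' segment downstream (and upstream), built by [flank_segments()] from the
#' nearest changepoint or chromosome boundary. The inner comparison is a
#' two-sided Kolmogorov-Smirnov test for continuous features or Fisher's
#' exact test on event counts. Each inner p-value is then referred to an
#' empirical null of inner p-values from random (changepoint, partner)
#' boundary pairs drawn from the profile's bins with at least one bin of
#' separation; a direction is significant when `(1 + #{null p <= observed
#' p}) / (n_valid + 1) < alpha`, and the changepoint is flagged when
#' either direction is.
#'
#' @param profile a `signature_profile`.
#' @param feature feature data frame; continuous features carry numeric
#'   `value` per window, counts features are event intervals.
#' @param kind "counts" or "continuous".
#' @param layout a [genome_layout()] (chromosome bounds for flanks).
#' @param window tile width for counts features (default 1 Mb).
#' @param n_null number of null pairs (default 10000).
#' @param alpha significance level.
#' @param seed integer seed.
#' @return data frame of class `flank_test` rows: `boundary`, `chrom`,
#'   `p_cd`, `p_cu` (inner p-values, NA when a segment holds no feature
#'   windows), `emp_p_cd`, `emp_p_cu`, `significant_downstream`,
#'   `significant_upstream`, `significant_any`. The null p-values are
#'   attached as attribute `null_p`.
#' @export
flank_test <- function(profile, feature, kind = c("counts", "continuous"),
                       layout, window = 1e6, n_null = 10000, alpha = 0.05,
                       seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(profile, "signature_profile"))
  cps <- profile$changepoints
  if (nrow(cps) == 0) stop("profile has no changepoints to test")
  series <- profile$series
  adm <- admissible_boundaries(series)
  adm_iv <- do.call(rbind, lapply(adm, function(b)
    boundary_interval(series, b)))
  adm_mid <- (adm_iv$start + adm_iv$end) / 2
  chrom_len <- function(ch) layout$length[match(ch, layout$chrom)]

  seg_p <- function(chrom, mid_c, mid_n) {
    fs <- flank_segments(mid_c, mid_n, chrom_len(chrom))
    x_cp <- segment_feature_sample(feature, chrom, fs$changepoint[1],
                                   fs$changepoint[2], kind, window)
    x_fl <- segment_feature_sample(feature, chrom, fs$flank[1],
                                   fs$flank[2], kind, window)
    inner_flank_test(x_cp, x_fl, kind)
  }

  # empirical null: random boundary plus a random downstream partner at
  # least one bin away (the chromosome end when none exists), mirroring
  # the observed construction; shared across this profile's changepoints
  set.seed(seed)
  null_p <- rep(NA_real_, n_null)
  for (i in seq_len(n_null)) {
    a <- sample(seq_along(adm), 1)
    partners <- which(adm_iv$chrom == adm_iv$chrom[a] & adm >= adm[a] + 2)
    mid_b <- if (length(partners) == 0) chrom_len(adm_iv$chrom[a])
             else adm_mid[if (length(partners) == 1) partners
                          else sample(partners, 1)]
    null_p[i] <- seg_p(adm_iv$chrom[a], adm_mid[a], mid_b)
  }
  null_p <- null_p[!is.na(null_p)]
  if (length(null_p) == 0)
    warning("all null draws produced empty feature segments")

  emp <- function(p) {
    if (is.na(p)) return(NA_real_)
    (1 + sum(null_p <= p)) / (length(null_p) + 1)
  }

  rows <- lapply(seq_len(nrow(cps)), function(k) {
    ch <- cps$chrom[k]
    mid <- (cps$start[k] + cps$end[k]) / 2
    same <- which(cps$chrom == ch)
    mids <- (cps$start[same] + cps$end[same]) / 2
    down <- mids[mids > mid]
    up <- mids[mids < mid]
    mid_d <- if (length(down) > 0) min(down) else chrom_len(ch)
    mid_u <- if (length(up) > 0) max(up) else 0
    p_cd <- seg_p(ch, mid, mid_d)
    p_cu <- seg_p(ch, mid, mid_u)
    e_cd <- emp(p_cd); e_cu <- emp(p_cu)
    s_cd <- !is.na(e_cd) && e_cd < alpha
    s_cu <- !is.na(e_cu) && e_cu < alpha
    data.frame(boundary = cps$boundary[k], chrom = ch,
               p_cd = p_cd, p_cu = p_cu, emp_p_cd = e_cd, emp_p_cu = e_cu,
               significant_downstream = s_cd, significant_upstream = s_cu,
               significant_any = s_cd || s_cu, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$p_cd) || anyNA(out$p_cu))
    message("inner test skipped for direction(s) with no feature windows")
  attr(out, "null_p") <- null_p
  class(out) <- c("flank_test", class(out))
  out
}
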