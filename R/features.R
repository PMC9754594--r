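#' Detect kataegis events
#'
#' A kataegis event is a maximal run of six or more consecutive mutations
#' on one chromosome whose mean successive-gap is at most 1,000 bp
#' (rainfall criterion). A window of mutations i..j qualifies when
#' `(pos_j - pos_i) / (j - i) <= max_mean_gap` and `j - i + 1 >=
#' min_mutations`; overlapping qualifying windows are merged into their
#' maximal extension, which makes the output unique.
#'
#' @param mutations mutation data frame (`sample`, `chrom`, `pos`), any
#'   order; sorted internally per sample.
#' @param min_mutations minimum run length (default 6).
#' @param max_mean_gap maximum mean inter-mutation distance in bp
#'   (default 1000).
#' @return data frame of events: `sample`, `chrom`, `start`, `end`
#'   (1-based positions of the first and last mutation in the run),
#'   `n_mutations`, `mean_gap`.
#' @export
detect_kataegis <- function(mutations, min_mutations = 6,
                            max_mean_gap = 1000) {
  samples <- if (!is.null(mutations$sample)) mutations$sample else "sample"
  out <- list()
  for (sid in unique(samples)) {
    mi <- mutations[samples == sid, , drop = FALSE]
    for (ch in unique(mi$chrom)) {
      pos <- sort(mi$pos[mi$chrom == ch])
      n <- length(pos)
      if (n < min_mutations) next
      k <- min_mutations - 1L
      # window (i, j) qualifies iff z_j <= z_i with j - i >= k, where
      # z_m = pos_m - max_mean_gap * m
      z <- pos - max_mean_gap * seq_len(n)
      iv <- list()
      for (i in seq_len(n - k)) {
        js <- which(z[(i + k):n] <= z[i])
        if (length(js) > 0)
          iv[[length(iv) + 1]] <- c(i, i + k - 1L + max(js))
      }
      if (length(iv) == 0) next
      m <- do.call(rbind, iv)
      m <- m[order(m[, 1]), , drop = FALSE]
      # merge index-overlapping qualifying windows
      merged <- list(m[1, ])
      if (nrow(m) > 1) for (r in 2:nrow(m)) {
        cur <- merged[[length(merged)]]
        if (m[r, 1] <= cur[2])
          merged[[length(merged)]] <- c(cur[1], max(cur[2], m[r, 2]))
        else merged[[length(merged) + 1]] <- m[r, ]
      }
      for (e in merged) {
        out[[length(out) + 1]] <- data.frame(
          sample = sid, chrom = ch, start = pos[e[1]], end = pos[e[2]],
          n_mutations = e[2] - e[1] + 1L,
          mean_gap = (pos[e[2]] - pos[e[1]]) / (e[2] - e[1]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_mutations = integer(0), mean_gap = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(match(res$chrom, canonical_chromosomes()), res$start), ,
      drop = FALSE]
}

# tiled or sliding windows over a layout as a GRanges
window_granges <- function(layout, window, step = window) {
  sl <- stats::setNames(layout$length, layout$chrom)
  if (step == window) {
    GenomicRanges::tileGenome(sl, tilewidth = window,
                              cut.last.tile.in.chrom = TRUE)
  } else {
    whole <- GenomicRanges::GRanges(layout$chrom,
                                    IRanges::IRanges(1, layout$length))
    unlist(GenomicRanges::slidingWindows(whole, width = window, step = step))
  }
}

# feature df (0-based half-open) to GRanges
track_granges <- function(track) {
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(track$start + 1, track$end))
}

# GRanges windows + counts back to a density-track df
granges_density <- function(win, value, window, step, normalize) {
  value <- as.numeric(value)
  if (normalize) {
    rng <- range(value)
    value <- if (diff(rng) == 0) rep(0, length(value))
             else (value - rng[1]) / diff(rng)
  }
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(win)),
                    start = GenomicRanges::start(win) - 1,
                    end = GenomicRanges::end(win),
                    value = value, stringsAsFactors = FALSE)
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "normalized") <- normalize
  out
}

#' Gene density track
#'
#' Counts gene records overlapping tiled windows (1 kb by default) across
#' the genome. With `normalize = TRUE` values are min-max scaled so the
#' densest window is one and the sparsest zero.
#'
#' @param genes gene intervals as a feature data frame (`chrom`, `start`,
#'   `end`, 0-based half-open), e.g. from [read_feature_track()] on a GFF.
#' @param layout a [genome_layout()].
#' @param window window width in bp (default 1000).
#' @param step window step (defaults to `window`, i.e. tiled).
#' @param normalize min-max scale the counts.
#' @return Density-track data frame (`chrom`, `start`, `end`, `value`).
#' @export
gene_density <- function(genes, layout, window = 1000, step = window,
                         normalize = FALSE) {
  win <- window_granges(layout, window, step)
  counts <- if (nrow(genes) == 0) rep(0L, length(win))
            else GenomicRanges::countOverlaps(win, track_granges(genes))
  granges_density(win, counts, window, step, normalize)
}

#' Event density track
#'
#' Counts events (e.g. kataegis events or CNAs) within tiled windows
#' (1 Mb by default) across the genome.
#'
#' @param events feature data frame of event intervals (0-based
#'   half-open); a kataegis table's `start`/`end` (1-based positions) can
#'   be converted with `start - 1`.
#' @param layout a [genome_layout()].
#' @param window window width in bp (default 1e6).
#' @param step window step (defaults to `window`).
#' @param normalize min-max scale the counts.
#' @return Density-track data frame.
#' @export
event_density <- function(events, layout, window = 1e6, step = window,
                          normalize = FALSE) {
  gene_density(events, layout, window = window, step = step,
               normalize = normalize)
}

#' Copy-number aberration intervals
#'
#' Keeps copy-number segments whose total ploidy differs from diploid.
#' Copy-number calls cover autosomes only, so X and Y are filtered out.
#'
#' @param segments feature data frame with `value` = total ploidy.
#' @return The aberrant autosomal segments.
#' @export
cna_intervals <- function(segments) {
  keep <- segments$value != 2 & !segments$chrom %in% c("X", "Y")
  out <- segments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus replication timing across cell lines
#'
#' Per-segment median of replication-timing tracks sharing one
#' segmentation.
#'
#' @param tracks list of density-track data frames with identical
#'   `chrom`/`start`/`end`.
#' @return A single track with the per-segment median in `value`.
#' @export
replication_timing_consensus <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  ref <- tracks[[1]][, c("chrom", "start", "end")]
  for (t in tracks[-1]) {
    if (!identical(ref, t[, c("chrom", "start", "end")]))
      stop("replication-timing tracks have mismatched segmentations")
  }
  vals <- vapply(tracks, function(t) as.numeric(t$value),
                 numeric(nrow(ref)))
  ref$value <- apply(as.matrix(vals), 1, stats::median)
  ref
}

#' Recode A/B chromatin compartments numerically
#'
#' A (open) becomes 1, B (closed) becomes 0, for use as a counts feature
#' in Fisher tables of A- vs B-compartment windows per segment.
#'
#' @param track feature data frame with `value` in {"A", "B"}.
#' @return The track with numeric `value`.
#' @export
recode_compartments <- function(track) {
  v <- as.character(track$value)
  if (!all(v %in% c("A", "B")))
    stop("compartment labels must be A or B")
  track$value <- ifelse(v == "A", 1, 0)
  track
}

#' Distance from each changepoint to the nearest event
#'
#' Zero when a changepoint interval overlaps an event; otherwise the gap
#' between closest edges. Events on other chromosomes contribute distances
#' along the genome-wise end-to-end concatenation in canonical order — a
#' reporting convention (values can exceed any chromosome length), not a
#' biological distance.
#'
#' @param changepoints data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param events data frame with `chrom`, `start`, `end`.
#' @param layout a [genome_layout()].
#' @return Numeric vector of distances (bp), one per changepoint.
#' @export
nearest_event_distance <- function(changepoints, events, layout) {
  if (nrow(events) == 0) stop("no events to measure distances to")
  off <- chrom_offsets(layout)
  cs <- off[changepoints$chrom] + changepoints$start
  ce <- off[changepoints$chrom] + changepoints$end
  es <- off[events$chrom] + events$start
  ee <- off[events$chrom] + events$end
  vapply(seq_along(cs), function(i) {
    gap <- pmax(es - ce[i], cs[i] - ee, 0)
    min(gap)
  }, numeric(1))
}
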