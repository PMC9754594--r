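#' Synthetic signature catalog with controlled separability
#'
#' Builds up to six synthetic signatures deterministically: signature s
#' concentrates its mass uniformly on its own block of 16 channels and
#' spreads a fraction `overlap` uniformly over all 96, so pairwise cosine
#' similarity grows smoothly from 0 (`overlap = 0`, orthogonal supports)
#' towards 1. This keeps tests self-contained and lets identifiability be
#' tuned; real COSMIC-style files load through
#' [read_signature_catalog()].
#'
#' @param n_signatures number of signatures (1..6).
#' @param overlap fraction of each signature's mass spread over all
#'   channels (in `[0, 1)`; default 0.15).
#' @return A [signature_catalog()] with names "SYN1".."SYNn".
#' @export
synthetic_catalog <- function(n_signatures = 4, overlap = 0.15) {
  stopifnot(n_signatures >= 1, n_signatures <= 6,
            overlap >= 0, overlap < 1)
  m <- matrix(overlap / 96, n_signatures, 96,
              dimnames = list(paste0("SYN", seq_len(n_signatures)),
                              sbs96_labels()))
  for (s in seq_len(n_signatures)) {
    block <- ((s - 1) * 16 + 1):(s * 16)
    m[s, block] <- m[s, block] + (1 - overlap) / 16
  }
  signature_catalog(m)
}

#' Sample channel counts from a signature mixture
#'
#' One multinomial draw of `n` mutations from the mixture distribution
#' `sum_s pi_s mu_s` over the 96 channels.
#'
#' @param activity activity vector over the catalog's signatures.
#' @param catalog a [signature_catalog()].
#' @param n number of mutations.
#' @return Integer length-96 count vector.
#' @export
simulate_counts <- function(activity, catalog, n) {
  stopifnot(length(activity) == nrow(catalog))
  p <- as.vector(crossprod(unclass(catalog), activity / sum(activity)))
  as.integer(stats::rmultinom(1, n, p))
}

#' Assemble a simulation configuration
#'
#' Declares a synthetic genome: a layout, a catalog, planted
#' constant-activity segments that tile the genome, a total mutation
#' count, a positional density model, and optional kataegis clusters and
#' feature tracks. `segments` rows carry genomic intervals (0-based
#' half-open) and the `activity` matrix one activity vector per segment.
#'
#' @param layout a [genome_layout()].
#' @param catalog a [signature_catalog()].
#' @param segments data frame with `chrom`, `start`, `end`; per
#'   chromosome the intervals must tile `[0, length)`.
#' @param activity numeric matrix, one row per segment row, columns = the
#'   catalog signatures; rows sum to 1.
#' @param n_mutations total mutations to emit.
#' @param density "uniform" (constant rate) or "piecewise" (per-segment
#'   `rate` multipliers, decoupling mutation-density changes from
#'   activity changes).
#' @param rate optional per-segment positive rate multipliers
#'   (piecewise mode).
#' @param kataegis optional data frame of clusters to inject: `chrom`,
#'   `center` (bp), `n`, `mean_gap` (bp), `channel` (1..96).
#' @param seed integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(layout, catalog, segments, activity,
                              n_mutations, density = c("uniform", "piecewise"),
                              rate = NULL, kataegis = NULL, seed = 1) {
  density <- match.arg(density)
  stopifnot(inherits(layout, "genome_layout"),
            inherits(catalog, "signature_catalog"),
            nrow(activity) == nrow(segments),
            ncol(activity) == nrow(catalog),
            n_mutations >= 1)
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    s <- s[order(s$start), ]
    len <- layout$length[match(ch, layout$chrom)]
    if (s$start[1] != 0 || s$end[nrow(s)] != len ||
        (nrow(s) > 1 && any(s$start[-1] != s$end[-nrow(s)])))
      stop("planted segments must tile chromosome ", ch)
  }
  if (density == "piecewise") {
    stopifnot(!is.null(rate), length(rate) == nrow(segments), all(rate > 0))
  } else rate <- rep(1, nrow(segments))
  if (any(abs(rowSums(activity) - 1) > 1e-9))
    stop("activity rows must sum to 1")
  structure(list(layout = layout, catalog = catalog, segments = segments,
                 activity = activity, n_mutations = n_mutations,
                 density = density, rate = rate, kataegis = kataegis,
                 seed = seed),
            class = "simulation_config")
}

#' Simulate a genome with planted activity regimes
#'
#' Draws mutation positions from the configured positional density,
#' assigns each mutation's channel from its segment's signature mixture,
#' synthesizes the trinucleotide context and ref/alt from the channel
#' label, and injects any configured kataegis clusters. Deterministic
#' given the config seed.
#'
#' @param config a [simulation_config()].
#' @param sample_id sample label (default "sim").
#' @return List with `mutations` (a mutation data frame with `channel`)
#'   and `truth` (planted changepoint coordinates, per-segment
#'   activities, kataegis events, config).
#' @export
simulate_sample <- function(config, sample_id = "sim") {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  segs <- config$segments
  widths <- segs$end - segs$start
  w <- widths * config$rate
  n_seg <- as.vector(stats::rmultinom(1, config$n_mutations, w / sum(w)))
  if (any(n_seg == 0 & w > 0))
    warning("planted segment received no mutations")
  labs <- sbs96_labels()
  mu <- unclass(config$catalog)
  parts <- lapply(seq_len(nrow(segs)), function(k) {
    n <- n_seg[k]
    if (n == 0) return(NULL)
    pos <- segs$start[k] + floor(stats::runif(n) * widths[k]) + 1 # 1-based
    p <- as.vector(crossprod(mu, config$activity[k, ]))
    chan <- sample.int(96, n, replace = TRUE, prob = p)
    data.frame(sample = sample_id, chrom = segs$chrom[k], pos = as.integer(pos),
               channel = chan, stringsAsFactors = FALSE)
  })
  mut <- do.call(rbind, parts)
  # kataegis clusters: tight runs with a biased channel
  kat_truth <- NULL
  if (!is.null(config$kataegis) && nrow(config$kataegis) > 0) {
    kat <- config$kataegis
    kparts <- lapply(seq_len(nrow(kat)), function(k) {
      gaps <- ceiling(stats::runif(kat$n[k] - 1, 1, 2 * kat$mean_gap[k] - 1))
      pos <- as.integer(kat$center[k] + cumsum(c(0, gaps)))
      data.frame(sample = sample_id, chrom = kat$chrom[k], pos = pos,
                 channel = kat$channel[k], stringsAsFactors = FALSE)
    })
    kat_truth <- do.call(rbind, lapply(kparts, function(p)
      data.frame(chrom = p$chrom[1], start = min(p$pos), end = max(p$pos),
                 n_mutations = nrow(p), stringsAsFactors = FALSE)))
    mut <- rbind(mut, do.call(rbind, kparts))
  }
  mut$context <- paste0(substr(labs[mut$channel], 1, 1),
                        substr(labs[mut$channel], 3, 3),
                        substr(labs[mut$channel], 7, 7))
  mut$ref <- substr(labs[mut$channel], 3, 3)
  mut$alt <- substr(labs[mut$channel], 5, 5)
  mut <- mut[order_genomic(mut$chrom, mut$pos),
             c("sample", "chrom", "pos", "ref", "alt", "context", "channel")]
  rownames(mut) <- NULL

  # planted changepoints: within-chromosome boundaries between segments
  # with differing activities
  cp <- list()
  for (ch in unique(segs$chrom)) {
    i <- which(segs$chrom == ch)
    i <- i[order(segs$start[i])]
    if (length(i) < 2) next
    for (k in seq_len(length(i) - 1)) {
      a <- config$activity[i[k], ]; b <- config$activity[i[k + 1], ]
      if (changepoint_magnitude(a, b) > 1e-12)
        cp[[length(cp) + 1]] <- data.frame(chrom = ch, pos = segs$end[i[k]],
                                           stringsAsFactors = FALSE)
    }
  }
  truth <- list(
    changepoints = if (length(cp)) do.call(rbind, cp)
                   else data.frame(chrom = character(0), pos = numeric(0)),
    activity = config$activity, segments = segs,
    kataegis = kat_truth, config = config)
  list(mutations = mut, truth = truth)
}

#' Random feature track
#'
#' Uniformly placed intervals with optional values, for association-test
#' simulations.
#'
#' @param layout a [genome_layout()].
#' @param n number of intervals.
#' @param width interval width in bp.
#' @param values optional vector recycled over intervals.
#' @param seed integer seed.
#' @return Feature data frame (`chrom`, `start`, `end`, `value`).
#' @export
simulate_feature_track <- function(layout, n, width, values = NA, seed = 1) {
  set.seed(seed)
  ci <- sample.int(nrow(layout), n, replace = TRUE,
                   prob = layout$length / sum(layout$length))
  start <- floor(stats::runif(n) * pmax(layout$length[ci] - width, 1))
  out <- data.frame(chrom = layout$chrom[ci], start = start,
                    end = pmin(start + width, layout$length[ci]),
                    value = rep_len(values, n), stringsAsFactors = FALSE)
  out[order(match(out$chrom, canonical_chromosomes()), out$start), ,
      drop = FALSE]
}

# maximum bipartite matching (augmenting paths); adj[[i]] = candidate
# truth indices for detected i. Returns matched truth index per detected
# (NA if unmatched).
max_bipartite_match <- function(adj, n_truth) {
  match_t <- rep(NA_integer_, n_truth)
  seen <- logical(n_truth)
  try_assign <- function(i) {
    for (t in adj[[i]]) {
      if (seen[t]) next
      seen[t] <<- TRUE
      if (is.na(match_t[t]) || try_assign(match_t[t])) {
        match_t[t] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in seq_along(adj)) {
    seen <- logical(n_truth)
    try_assign(i)
  }
  match_d <- rep(NA_integer_, length(adj))
  ok <- !is.na(match_t)
  match_d[match_t[ok]] <- which(ok)
  match_d
}

#' Score changepoint recovery against a planted truth
#'
#' Matches detected changepoints to planted ones one-to-one (maximum
#' bipartite matching): a detected interval matches a planted position on
#' the same chromosome when the position lies within the interval widened
#' by `tolerance_bp`. Precision is matched/detected, recall is
#' matched/planted; with no detections, precision is reported as 1 by
#' convention (flagged via `n_detected = 0`).
#'
#' @param truth data frame of planted changepoints (`chrom`, `pos`).
#' @param detected data frame of detected changepoints (`chrom`, `start`,
#'   `end`), e.g. a profile's `changepoints`.
#' @param tolerance_bp widening applied to each detected interval.
#' @return List: `precision`, `recall`, `n_matched`, `n_detected`,
#'   `n_truth`, `boundary_error` (mean |detected midpoint - planted
#'   position| over matches, NA if none).
#' @export
evaluate_recovery <- function(truth, detected, tolerance_bp = 0) {
  n_t <- nrow(truth); n_d <- nrow(detected)
  if (n_d == 0)
    return(list(precision = 1, recall = if (n_t == 0) 1 else 0,
                n_matched = 0L, n_detected = 0L, n_truth = n_t,
                boundary_error = NA_real_))
  adj <- lapply(seq_len(n_d), function(i)
    which(truth$chrom == detected$chrom[i] &
            truth$pos >= detected$start[i] - tolerance_bp &
            truth$pos <= detected$end[i] + tolerance_bp))
  m <- max_bipartite_match(adj, n_t)
  n_match <- sum(!is.na(m))
  err <- if (n_match == 0) NA_real_ else {
    i <- which(!is.na(m))
    mean(abs((detected$start[i] + detected$end[i]) / 2 - truth$pos[m[i]]))
  }
  list(precision = n_match / n_d, recall = if (n_t == 0) 1 else n_match / n_t,
       n_matched = n_match, n_detected = n_d, n_truth = n_t,
       boundary_error = err)
}
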