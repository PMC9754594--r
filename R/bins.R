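#' Aggregate mutations into equal-count genomic bins
#'
#' Mutations (ordered by chromosomal coordinate) are partitioned into bins
#' of `bin_size` mutations each. In genome-wise mode the chromosomes are
#' treated as laid end-to-end in canonical order and the terminal bin
#' absorbs the remainder (it may exceed `bin_size`). In chromosome-wise
#' mode the same rule is applied independently per chromosome, so no bin
#' spans two chromosomes. A chromosome (or genome) with fewer than
#' `bin_size` mutations forms one undersized bin, flagged with a warning
#' since activity estimates from fewer than ~100 mutations are unreliable.
#'
#' @param mutations mutation data frame with columns `chrom`, `pos` and
#'   either `channel` or `context`+`alt` (channels are computed if absent).
#' @param bin_size target number of mutations per bin (default 100).
#' @param mode "genome" (genome-wise) or "chromosome" (chromosome-wise).
#' @param sample_id optional sample label stored on the series.
#' @return A `bin_series` object: list with `bins` (data frame: `bin`,
#'   `chrom_start`, `pos_start`, `chrom_end`, `pos_end`, `n`), `counts`
#'   (B x 96 integer matrix), `mode`, `bin_size`, `sample_id`, and the
#'   binned `mutations`.
#' @export
make_bins <- function(mutations, bin_size = 100,
                      mode = c("genome", "chromosome"), sample_id = NULL) {
  mode <- match.arg(mode)
  if (is.null(mutations) || nrow(mutations) == 0)
    stop("cannot bin an empty mutation set")
  stopifnot(bin_size >= 1)
  if (is.null(mutations$channel))
    mutations <- mutation_channels(mutations)
  if (is.null(sample_id))
    sample_id <- if (!is.null(mutations$sample)) mutations$sample[1] else "sample"
  make_bins_ordered(mutations, bin_size, mode,
                    chrom_order = canonical_chromosomes(),
                    sample_id = sample_id)
}

# binning under an explicit chromosome order (used by the chromosome-order
# bootstrap); mutations re-sorted internally
make_bins_ordered <- function(mutations, bin_size, mode, chrom_order,
                              sample_id) {
  ord <- order(match(mutations$chrom, chrom_order), mutations$pos)
  mutations <- mutations[ord, , drop = FALSE]
  rownames(mutations) <- NULL

  assign_bins <- function(n) {
    b <- max(1L, n %/% bin_size)
    idx <- pmin(((seq_len(n) - 1L) %/% bin_size) + 1L, b)
    list(n_bins = b, idx = idx)
  }

  if (mode == "genome") {
    a <- assign_bins(nrow(mutations))
    if (nrow(mutations) < bin_size)
      warning("fewer than bin_size mutations in total; one undersized bin")
    bin_idx <- a$idx
  } else {
    chroms <- unique(mutations$chrom)
    bin_idx <- integer(nrow(mutations))
    off <- 0L
    for (ch in chroms) {
      i <- which(mutations$chrom == ch)
      if (length(i) < bin_size)
        warning("chromosome ", ch, " has fewer than bin_size mutations; ",
                "kept as one undersized bin")
      a <- assign_bins(length(i))
      bin_idx[i] <- a$idx + off
      off <- off + a$n_bins
    }
  }

  B <- max(bin_idx)
  first <- match(seq_len(B), bin_idx)
  last <- length(bin_idx) - match(seq_len(B), rev(bin_idx)) + 1L
  bins <- data.frame(
    bin = seq_len(B),
    chrom_start = mutations$chrom[first],
    pos_start = mutations$pos[first],
    chrom_end = mutations$chrom[last],
    pos_end = mutations$pos[last],
    n = tabulate(bin_idx, B),
    stringsAsFactors = FALSE)

  counts <- matrix(0L, B, 96, dimnames = list(NULL, sbs96_labels()))
  tab <- table(factor(bin_idx, levels = seq_len(B)),
               factor(mutations$channel, levels = 1:96))
  counts[] <- as.integer(tab)

  structure(list(bins = bins, counts = counts, mode = mode,
                 bin_size = bin_size, sample_id = sample_id,
                 mutations = mutations, chrom_order = chrom_order),
            class = "bin_series")
}

#' @export
print.bin_series <- function(x, ...) {
  cat("bin_series: ", nrow(x$bins), " bins of ~", x$bin_size,
      " mutations (", x$mode, "-wise), sample ", x$sample_id, "\n", sep = "")
  invisible(x)
}

#' Re-bin a genome-wise series under a random chromosome order
#'
#' In the genome-wise setting the end-to-end chromosome concatenation is a
#' numbering convention, so placement uncertainty can be probed by
#' randomizing the order of chromosomes and re-binning. Mutation content is
#' conserved.
#'
#' @param series a genome-wise `bin_series`.
#' @param seed integer seed; the identity permutation is used only if the
#'   drawn permutation happens to be it.
#' @return A new `bin_series` under the permuted chromosome order (stored
#'   in `$chrom_order`).
#' @export
chromosome_order_shuffle <- function(series, seed) {
  stopifnot(inherits(series, "bin_series"))
  if (series$mode != "genome")
    stop("chromosome order shuffling applies to genome-wise series only")
  present <- unique(series$mutations$chrom)
  set.seed(seed)
  perm <- sample(present)
  full <- c(perm, setdiff(canonical_chromosomes(), perm))
  make_bins_ordered(series$mutations, series$bin_size, "genome",
                    chrom_order = full, sample_id = series$sample_id)
}

# genomic interval (0-based half-open) around boundary b of a series:
# union of the spans of bin b and bin b+1. Cross-chromosome boundaries
# (genome-wise only) are reported on the right bin's chromosome.
boundary_interval <- function(series, b) {
  bins <- series$bins
  stopifnot(b >= 1, b <= nrow(bins) - 1)
  l <- bins[b, ]; r <- bins[b + 1, ]
  if (l$chrom_start == r$chrom_end) {
    data.frame(chrom = r$chrom_end, start = l$pos_start - 1, end = r$pos_end,
               cross_chrom = FALSE, stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = r$chrom_start, start = r$pos_start - 1, end = r$pos_end,
               cross_chrom = TRUE, stringsAsFactors = FALSE)
  }
}

#' Write a bin table
#'
#' Tab-separated table of bin spans (1-based mutation positions) and the 96
#' channel counts.
#'
#' @param series a `bin_series`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bin_table <- function(series, path) {
  df <- cbind(series$bins, as.data.frame(series$counts, check.names = FALSE))
  names(df)[1] <- "bin_index"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
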