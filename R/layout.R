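#' Canonical chromosome labels
#'
#' The canonical human chromosome ordering used for genome-wise
#' concatenation: autosomes 1--22 followed by X and Y. All coordinates in
#' the package are expressed on chromosomes with these labels (no "chr"
#' prefix).
#'
#' @return Character vector of the 24 canonical labels, in order.
#' @export
canonical_chromosomes <- function() {
  c(as.character(1:22), "X", "Y")
}

#' Normalize chromosome labels
#'
#' Strips a leading "chr" prefix so UCSC-style ("chr1") and plain ("1")
#' labels interoperate. Labels that are not canonical after stripping are
#' returned as NA.
#'
#' @param chrom character vector of chromosome labels.
#' @return Character vector of canonical labels, NA where non-canonical.
#' @export
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  x[!x %in% canonical_chromosomes()] <- NA_character_
  x
}

#' Construct a genome layout
#'
#' A genome layout records the ordered chromosomes and their lengths and is
#' the coordinate frame for binning, sliding windows and genome-wise
#' concatenated coordinates. Optional centromere positions are carried as
#' plotting metadata only.
#'
#' @param chrom character vector of canonical chromosome labels.
#' @param length integer vector of chromosome lengths in bp (> 0).
#' @param centromere optional numeric vector of centromere midpoints in bp.
#' @return A `genome_layout` data frame with columns `chrom`, `length`
#'   (and `centromere` if given), ordered canonically.
#' @export
genome_layout <- function(chrom, length, centromere = NULL) {
  chrom <- normalize_chrom(chrom)
  if (anyNA(chrom)) stop("non-canonical chromosome label in layout")
  if (anyDuplicated(chrom)) stop("duplicated chromosome in layout")
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  ord <- order(match(chrom, canonical_chromosomes()))
  out <- data.frame(chrom = chrom[ord], length = as.numeric(length)[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(centromere)) out$centromere <- as.numeric(centromere)[ord]
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Genome-wise concatenated offsets
#'
#' Offsets of each chromosome start when chromosomes are laid end-to-end in
#' canonical order; used for cross-chromosome distance reporting.
#'
#' @param layout a [genome_layout()].
#' @return Named numeric vector of 0-based offsets, one per chromosome.
#' @export
chrom_offsets <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  off <- cumsum(c(0, layout$length[-nrow(layout)]))
  names(off) <- layout$chrom
  off
}

# order mutations by (canonical chromosome, position); drops nothing
order_genomic <- function(chrom, pos) {
  order(match(chrom, canonical_chromosomes()), pos)
}
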