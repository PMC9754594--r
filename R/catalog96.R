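#' The 96 canonical SBS channel labels
#'
#' Single-base substitutions are represented on the pyrimidine strand, giving
#' six substitution classes (C>A, C>G, C>T, T>A, T>C, T>G), each expanded by
#' the 5' then the 3' flanking base in order A, C, G, T: 6 x 4 x 4 = 96
#' channels. Labels follow the COSMIC "A[C>A]A" convention.
#'
#' @return Character vector of the 96 labels in canonical order.
#' @export
sbs96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(96)
  i <- 1L
  for (s in subs) for (b5 in bases) for (b3 in bases) {
    out[i] <- paste0(b5, "[", s, "]", b3)
    i <- i + 1L
  }
  out
}

# reverse complement of a vector of DNA strings
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Classify mutations into SBS96 channels
#'
#' Maps (trinucleotide context, alternate base) pairs onto the 96 canonical
#' channels. Mutations whose reference (the middle base of the context) is a
#' purine are reverse-complemented first, so the returned channel always has
#' a pyrimidine reference: classification is strand-involutive.
#'
#' @param context character vector of 3-mers centered on the mutated base
#'   (A/C/G/T only).
#' @param alt character vector of alternate bases.
#' @return Integer vector of channel indices in 1..96, named with the
#'   canonical labels. Contexts containing N (or any non-ACGT letter) or
#'   alt equal to the reference yield NA.
#' @export
classify_sbs96 <- function(context, alt) {
  context <- toupper(as.character(context))
  alt <- toupper(as.character(alt))
  stopifnot(length(context) == length(alt))
  ok <- grepl("^[ACGT]{3}$", context) & alt %in% c("A", "C", "G", "T")
  ref <- substr(context, 2, 2)
  ok <- ok & ref != alt
  # purine reference: flip to the pyrimidine strand
  pur <- ok & ref %in% c("A", "G")
  if (any(pur)) {
    context[pur] <- revcomp(context[pur])
    alt[pur] <- chartr("ACGT", "TGCA", alt[pur])
    ref[pur] <- substr(context[pur], 2, 2)
  }
  lab <- paste0(substr(context, 1, 1), "[", ref, ">", alt, "]",
                substr(context, 3, 3))
  idx <- match(lab, sbs96_labels())
  idx[!ok] <- NA_integer_
  names(idx) <- ifelse(ok, lab, NA_character_)
  idx
}

#' Annotate a mutation table with SBS96 channels
#'
#' @param mutations data frame with at least `context` and `alt` columns
#'   (as returned by [read_mutations()]).
#' @return The same data frame with an integer `channel` column (1..96).
#'   Rows that cannot be classified (e.g. context containing N) are dropped
#'   with a warning.
#' @export
mutation_channels <- function(mutations) {
  ch <- classify_sbs96(mutations$context, mutations$alt)
  if (anyNA(ch)) {
    warning(sum(is.na(ch)), " mutation(s) could not be classified and were dropped")
    mutations <- mutations[!is.na(ch), , drop = FALSE]
    ch <- ch[!is.na(ch)]
  }
  mutations$channel <- as.integer(ch)
  rownames(mutations) <- NULL
  mutations
}

#' Construct a signature catalog
#'
#' A catalog is an S x 96 matrix of emission probabilities: row s is the
#' probability distribution of signature s over the 96 SBS channels.
#' Rows are renormalized to sum to one.
#'
#' @param emissions numeric S x 96 matrix; columns must be the canonical
#'   channel labels (any order; they are reordered canonically).
#' @param names optional character vector of signature names (defaults to
#'   rownames of `emissions`).
#' @return A `signature_catalog` matrix (rows = signatures, columns = the
#'   96 canonical channels).
#' @export
signature_catalog <- function(emissions, names = NULL) {
  emissions <- as.matrix(emissions)
  if (ncol(emissions) != 96)
    stop("catalog must have 96 channel columns")
  labs <- colnames(emissions)
  if (is.null(labs) || !setequal(labs, sbs96_labels()) || anyDuplicated(labs))
    stop("catalog columns must be exactly the 96 canonical channel labels")
  emissions <- emissions[, sbs96_labels(), drop = FALSE]
  if (any(emissions < 0)) stop("negative emission probability in catalog")
  rs <- rowSums(emissions)
  if (any(rs <= 0)) stop("catalog row with zero total probability")
  emissions <- emissions / rs
  if (!is.null(names)) rownames(emissions) <- names
  if (is.null(rownames(emissions)))
    rownames(emissions) <- paste0("S", seq_len(nrow(emissions)))
  class(emissions) <- c("signature_catalog", class(emissions))
  emissions
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat("signature_catalog:", nrow(x), "signatures x 96 channels\n")
  cat("signatures:", paste(rownames(x), collapse = ", "), "\n")
  invisible(x)
}

#' Read a COSMIC-style signature matrix
#'
#' Accepts tab-separated matrices with signatures in columns and the 96
#' channels in rows (COSMIC v3 layout) or the transpose; the orientation is
#' detected from where the channel labels sit. Channels are mapped onto the
#' canonical internal ordering regardless of file row order and each
#' signature is renormalized to sum to one.
#'
#' @param path path to a tab-separated file.
#' @return A [signature_catalog()].
#' @export
read_signature_catalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  first <- as.character(df[[1]])
  if (all(first %in% sbs96_labels()) && nrow(df) == 96) {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- first
    m <- t(m)
  } else {
    # signatures in rows: first column holds signature names
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- first
  }
  storage.mode(m) <- "double"
  signature_catalog(m)
}

#' Write a signature catalog in COSMIC v3 layout
#'
#' Channels in rows (column `Type`), one column per signature.
#'
#' @param catalog a [signature_catalog()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_signature_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "signature_catalog"))
  df <- data.frame(Type = sbs96_labels(), t(unclass(catalog)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
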