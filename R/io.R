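#' Read somatic SNV calls
#'
#' Reads single-base substitutions from a VCF 4.x file or a tab-separated
#' mutation table with header columns `sample`, `chrom`, `pos`, `ref`,
#' `alt` and optionally `context`. Only biallelic single-base substitutions
#' are returned; multi-allelic VCF records are split and non-SNV alleles
#' dropped. Records on non-canonical contigs, and records whose
#' trinucleotide context contains N, are skipped with a warning. The number
#' of non-SNV records excluded is reported as a message and attached as
#' attribute `n_skipped`.
#'
#' Positions are 1-based. Output rows are sorted by (canonical chromosome
#' order, position).
#'
#' @param path path to the input file.
#' @param format "vcf", "tsv", or "auto" (by file extension).
#' @param reference optional reference genome: a FASTA path or a named
#'   `Biostrings::DNAStringSet`. Required when the input carries no
#'   `context` column (always for VCF).
#' @param sample_id sample identifier used for VCF input (defaults to the
#'   file base name); TSV input takes it from the `sample` column.
#' @return data frame with columns `sample`, `chrom`, `pos`, `ref`, `alt`,
#'   `context`.
#' @export
read_mutations <- function(path, format = c("auto", "vcf", "tsv"),
                           reference = NULL, sample_id = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    if (is.null(sample_id))
      sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
    # split multi-allelic records
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    n_alt <- lengths(alts)
    df <- data.frame(
      sample = sample_id,
      chrom = rep(fix$CHROM, n_alt),
      pos = rep(as.integer(fix$POS), n_alt),
      ref = rep(fix$REF, n_alt),
      alt = unlist(alts),
      stringsAsFactors = FALSE)
    df$context <- NA_character_
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("sample", "chrom", "pos", "ref", "alt")
    if (!all(need %in% names(df)))
      stop("mutation table must have columns: ", paste(need, collapse = ", "))
    df$pos <- as.integer(df$pos)
    if (is.null(df$context)) df$context <- NA_character_
  }
  df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)

  snv <- nchar(df$ref) == 1 & nchar(df$alt) == 1 &
    df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T") &
    df$ref != df$alt
  n_skipped <- sum(!snv)
  if (n_skipped > 0)
    message(n_skipped, " non-SNV record(s) excluded")
  df <- df[snv, , drop = FALSE]

  chrom <- normalize_chrom(df$chrom)
  if (anyNA(chrom)) {
    warning(sum(is.na(chrom)), " record(s) on non-canonical contigs dropped")
    df <- df[!is.na(chrom), , drop = FALSE]
    chrom <- chrom[!is.na(chrom)]
  }
  df$chrom <- chrom

  no_ctx <- is.na(df$context) | df$context == ""
  if (any(no_ctx)) {
    if (is.null(reference))
      stop("reference FASTA required: input lacks trinucleotide context")
    ctx <- fetch_context(reference, df$chrom[no_ctx], df$pos[no_ctx])
    bad_ref <- !is.na(ctx) & substr(ctx, 2, 2) != df$ref[no_ctx]
    if (any(bad_ref)) {
      warning(sum(bad_ref), " record(s) whose ref mismatches the reference dropped")
      ctx[bad_ref] <- NA_character_
    }
    df$context[no_ctx] <- ctx
  }
  df$context <- toupper(df$context)
  has_n <- !grepl("^[ACGT]{3}$", df$context)
  if (any(has_n)) {
    warning(sum(has_n), " record(s) with ambiguous context skipped")
    df <- df[!has_n, , drop = FALSE]
  }
  bad_mid <- substr(df$context, 2, 2) != df$ref
  if (any(bad_mid)) {
    warning(sum(bad_mid), " record(s) whose context middle base mismatches ref dropped")
    df <- df[!bad_mid, , drop = FALSE]
  }
  df <- df[order_genomic(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_skipped") <- n_skipped
  df
}

# extract 3-mers centered on pos from a FASTA path or DNAStringSet
fetch_context <- function(reference, chrom, pos) {
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  nm <- normalize_chrom(sub("\\s.*$", "", names(reference)))
  names(reference) <- nm
  out <- rep(NA_character_, length(chrom))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (!ch %in% nm) next
    seq <- reference[[ch]]
    p <- pos[i]
    okp <- p >= 2 & p <= length(seq) - 1
    v <- Biostrings::Views(seq, start = pmax(p - 1, 1), width = 3)
    out[i][okp] <- as.character(v)[okp]
  }
  out
}

#' Write a mutation table
#'
#' Tab-separated with header columns `sample`, `chrom`, `pos`, `ref`,
#' `alt`, `context` (1-based positions), readable by [read_mutations()].
#'
#' @param mutations mutation data frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_mutations <- function(mutations, path) {
  cols <- intersect(c("sample", "chrom", "pos", "ref", "alt", "context"),
                    names(mutations))
  utils::write.table(mutations[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genomic feature track
#'
#' Reads BED (0-based half-open; native convention), BED with a numeric
#' score, or GFF3/GTF (1-based closed, converted to 0-based half-open).
#' Overlapping intervals are preserved as-is. Intervals on non-canonical
#' contigs are dropped with a warning.
#'
#' @param path path to the track file.
#' @param format one of "bed", "bed_score", "gff".
#' @return data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `value` (numeric score, character label, or NA),
#'   sorted by (chromosome, start).
#' @export
read_feature_track <- function(path, format = c("bed", "bed_score", "gff")) {
  format <- match.arg(format)
  if (format == "gff") {
    gr <- rtracklayer::import(path)
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = GenomicRanges::end(gr),
      value = if (!is.null(gr$score)) as.numeric(gr$score) else NA,
      stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             comment.char = "#")
    df <- data.frame(chrom = as.character(raw[[1]]),
                     start = as.numeric(raw[[2]]),
                     end = as.numeric(raw[[3]]),
                     stringsAsFactors = FALSE)
    df$value <- NA
    if (format == "bed_score") {
      if (ncol(raw) >= 5) df$value <- utils::type.convert(raw[[5]], as.is = TRUE)
      else if (ncol(raw) == 4) df$value <- utils::type.convert(raw[[4]], as.is = TRUE)
      else stop("bed_score input needs a score column")
    }
  }
  bad <- df$start >= df$end
  if (any(bad))
    stop("interval with start >= end at line(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  chrom <- normalize_chrom(df$chrom)
  if (anyNA(chrom)) {
    warning(sum(is.na(chrom)), " interval(s) on non-canonical contigs dropped")
    df <- df[!is.na(chrom), , drop = FALSE]
    chrom <- chrom[!is.na(chrom)]
  }
  df$chrom <- chrom
  df <- df[order(match(df$chrom, canonical_chromosomes()), df$start), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a feature track as BED
#'
#' 0-based half-open coordinates; `value` written as a 5th (score) column
#' with a placeholder name column, so the file round-trips through
#' [read_feature_track()] with `format = "bed_score"`.
#'
#' @param track feature data frame (`chrom`, `start`, `end`, optional `value`).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_feature_track <- function(track, path) {
  has_val <- !is.null(track$value) && !all(is.na(track$value))
  df <- track[, c("chrom", "start", "end")]
  if (has_val) {
    df$name <- "."
    df$score <- track$value
  }
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
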