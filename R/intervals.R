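# Genomic intervals are plain data frames with columns chrom/start/end in the
# BED convention: 0-based start, half-open end. All modules share this single
# convention; GRanges (1-based closed) are built only transiently for overlap
# queries and never leave a function.

#' Construct a table of genomic intervals
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start.
#' @param end Integer vector, exclusive end; must satisfy `end > start`.
#' @param ... Further equal-length columns appended to the table.
#'
#' @return A data frame with columns `chrom`, `start`, `end` plus any extras,
#'   sorted by (chrom, start).
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  sort_intervals(df)
}

validate_intervals <- function(df, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    stop(what, " table must have columns chrom, start, end", call. = FALSE)
  }
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom))) {
    stop(what, ": chromosome names must be non-empty", call. = FALSE)
  }
  if (any(df$start < 0)) {
    stop(what, ": negative start coordinate", call. = FALSE)
  }
  if (any(df$end <= df$start)) {
    stop(what, ": end must be greater than start", call. = FALSE)
  }
  invisible(df)
}

sort_intervals <- function(df) {
  if (nrow(df) == 0) return(df)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# 0-based half-open -> GRanges (1-based closed)
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

#' @noRd
interval_midpoint <- function(df) {
  floor((df$start + df$end) / 2)
}

# warn when two inputs use disjoint chromosome vocabularies (typically a
# "chr1" vs "1" mismatch that would silently empty every join)
check_chrom_compat <- function(chroms_a, chroms_b, what_a = "first input",
                               what_b = "second input") {
  a <- unique(as.character(chroms_a))
  b <- unique(as.character(chroms_b))
  if (length(a) && length(b) && !length(intersect(a, b))) {
    warning(sprintf(
      "no chromosome names shared between %s and %s (union: %s)",
      what_a, what_b, paste(sort(union(a, b)), collapse = ", ")),
      call. = FALSE)
  }
  invisible(NULL)
}

# overlap hits between two 0-based half-open tables; returns a data.frame of
# row indices (query, subject) plus overlap width in bp
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(data.frame(query = integer(), subject = integer(),
                      width = numeric()))
  }
  hits <- GenomicRanges::findOverlaps(as_granges(query), as_granges(subject))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  width <- pmin(query$end[qi], subject$end[si]) -
    pmax(query$start[qi], subject$start[si])
  data.frame(query = qi, subject = si, width = width)
}
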