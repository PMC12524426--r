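# Readers and writers for the plain-text formats the pipeline touches:
# ENCODE narrowPeak, BED3/BED6, BEDPE, WashU longrange, a TSV gene table,
# a COO contact-matrix text format and TSV differential tables.

#' Read an ENCODE narrowPeak (or plain BED) file
#'
#' Accepts the 10-column narrowPeak dialect (BED6+4, column 7 = signalValue)
#' as well as 3- or 6-column BED, in which case the signal is set to 0.
#'
#' @param path Path to the file. Lines starting with `#` or `track` are
#'   skipped.
#' @param min_qvalue If not `NULL` and the file carries the narrowPeak
#'   q-value column (column 9, -log10 scale), peaks with
#'   `qValue < -log10(min_qvalue)` are dropped.
#'
#' @return Data frame with columns `chrom`, `start`, `end`, `name`, `signal`
#'   sorted by (chrom, start). Coordinates stay 0-based half-open.
#' @export
read_narrowpeak <- function(path, min_qvalue = NULL) {
  lines <- read_data_lines(path)
  if (length(lines) == 0) {
    return(empty_peaks())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  ok <- ncols %in% c(3L, 6L, 10L)
  if (!all(ok)) {
    stop(sprintf("malformed narrowPeak/BED line %d in %s: %d columns (expected 3, 6 or 10)",
                 which(!ok)[1], path, ncols[which(!ok)[1]]), call. = FALSE)
  }
  n <- length(fields)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.numeric(vapply(fields, `[[`, "", 2L))
  end <- as.numeric(vapply(fields, `[[`, "", 3L))
  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric coordinate in ", path, call. = FALSE)
  }
  if (any(start < 0)) {
    stop("negative coordinate in ", path, call. = FALSE)
  }
  name <- rep(NA_character_, n)
  signal <- rep(0, n)
  has6 <- ncols >= 6L
  name[has6] <- vapply(fields[has6], `[[`, "", 4L)
  has10 <- ncols == 10L
  if (any(has10)) {
    signal[has10] <- as.numeric(vapply(fields[has10], `[[`, "", 7L))
    if (anyNA(signal) || any(signal < 0)) {
      stop("invalid signalValue in ", path, call. = FALSE)
    }
    if (!is.null(min_qvalue)) {
      q <- as.numeric(vapply(fields[has10], `[[`, "", 9L))
      keep10 <- is.na(q) | q < 0 | q >= -log10(min_qvalue)
      keep <- !has10
      keep[has10] <- keep10
      chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
      name <- name[keep]; signal <- signal[keep]
    }
  }
  df <- data.frame(chrom = chrom, start = start, end = end, name = name,
                   signal = signal, stringsAsFactors = FALSE)
  validate_intervals(df, "peak")
  sort_intervals(df)
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), signal = numeric(), stringsAsFactors = FALSE)
}

read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
}

#' Write intervals as BED
#'
#' Emits BED6 when a `name` column is present (score column carries `signal`
#' if available), otherwise BED3. Rows are written sorted by (chrom, start).
#'
#' @param df Interval data frame (`chrom`, `start`, `end`, optionally `name`,
#'   `signal`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  df <- sort_intervals(df)
  if ("name" %in% names(df)) {
    name <- ifelse(is.na(df$name), ".", df$name)
    score <- if ("signal" %in% names(df)) df$signal else rep(0, nrow(df))
    out <- paste(df$chrom, fmt_pos(df$start), fmt_pos(df$end), name,
                 score, ".", sep = "\t")
  } else {
    out <- paste(df$chrom, fmt_pos(df$start), fmt_pos(df$end), sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

fmt_pos <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a gene table
#'
#' Tab-separated with header: `gene_id`, `chrom`, `tss`, `strand`,
#' `expression` (FPKM-like; the header name `fpkm` is also accepted).
#'
#' @param path Path to the TSV.
#' @return Data frame sorted by (chrom, tss) with the five columns above.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("fpkm" %in% names(df) && !"expression" %in% names(df)) {
    names(df)[names(df) == "fpkm"] <- "expression"
  }
  need <- c("gene_id", "chrom", "tss", "strand", "expression")
  if (!all(need %in% names(df))) {
    stop("gene table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- df[need]
  validate_genes(df)
  df <- df[order(df$chrom, df$tss, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

validate_genes <- function(df) {
  if (any(duplicated(df$gene_id))) {
    stop("duplicated gene_id in gene table", call. = FALSE)
  }
  if (any(df$tss < 0)) stop("gene table: negative TSS", call. = FALSE)
  if (!all(df$strand %in% c("+", "-"))) {
    stop("gene table: strand must be '+' or '-'", call. = FALSE)
  }
  if (any(df$expression < 0)) {
    stop("gene table: negative expression", call. = FALSE)
  }
  invisible(df)
}

#' Write a gene table
#' @param genes Gene data frame as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read loops from BEDPE
#'
#' First six columns are the two anchors; column 7 (if present) is a name
#' and column 8 (or 7 when numeric) the score. Anchors of every loop are
#' re-ordered so anchor1 starts first.
#'
#' @param path Path to the BEDPE file.
#' @return Data frame with `chrom1,start1,end1,chrom2,start2,end2,score`,
#'   sorted by (chrom1, start1).
#' @export
read_bedpe <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines) == 0) return(empty_loops())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 6L)) {
    stop(sprintf("malformed BEDPE line %d in %s: fewer than 6 columns",
                 which(ncols < 6L)[1], path), call. = FALSE)
  }
  get <- function(k) vapply(fields, function(f) f[[k]], "")
  df <- data.frame(
    chrom1 = get(1), start1 = as.numeric(get(2)), end1 = as.numeric(get(3)),
    chrom2 = get(4), start2 = as.numeric(get(5)), end2 = as.numeric(get(6)),
    score = NA_real_, stringsAsFactors = FALSE)
  if (all(ncols >= 8L)) {
    df$score <- suppressWarnings(as.numeric(get(8)))
  } else if (all(ncols >= 7L)) {
    df$score <- suppressWarnings(as.numeric(get(7)))
  }
  df$score[is.na(df$score)] <- 0
  canonicalize_loops(df)
}

empty_loops <- function() {
  data.frame(chrom1 = character(), start1 = numeric(), end1 = numeric(),
             chrom2 = character(), start2 = numeric(), end2 = numeric(),
             score = numeric(), stringsAsFactors = FALSE)
}

canonicalize_loops <- function(df) {
  if (nrow(df)) {
    swap <- df$chrom1 == df$chrom2 & df$start2 < df$start1
    if (any(swap)) {
      tmp <- df[swap, c("start1", "end1")]
      df[swap, c("start1", "end1")] <- df[swap, c("start2", "end2")]
      df[swap, c("start2", "end2")] <- tmp
    }
    if (any(df$start1 < 0 | df$start2 < 0)) {
      stop("loop with negative coordinate", call. = FALSE)
    }
    if (any(df$end1 <= df$start1 | df$end2 <= df$start2)) {
      stop("loop anchor with end <= start", call. = FALSE)
    }
    df <- df[order(df$chrom1, df$start1, df$start2), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write loops as BEDPE
#' @param loops Loop data frame as returned by [read_bedpe()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  loops <- canonicalize_loops(loops)
  out <- paste(loops$chrom1, fmt_pos(loops$start1), fmt_pos(loops$end1),
               loops$chrom2, fmt_pos(loops$start2), fmt_pos(loops$end2),
               ".", loops$score, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Write loops or scored pairs in WashU longrange format
#'
#' One line per loop: `chrom start end chrom2:start2-end2,score`, suitable
#' for browser display of enhancer-promoter links.
#'
#' @param loops Loop data frame (`chrom1,start1,end1,chrom2,start2,end2,score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_longrange <- function(loops, path) {
  loops <- canonicalize_loops(loops)
  out <- paste0(loops$chrom1, "\t", fmt_pos(loops$start1), "\t",
                fmt_pos(loops$end1), "\t", loops$chrom2, ":",
                fmt_pos(loops$start2), "-", fmt_pos(loops$end2), ",",
                loops$score)
  writeLines(out, path)
  invisible(path)
}

#' Read a differential table
#'
#' Tab-separated with header. Minimal form: `feature_id`, `log2fc`.
#' Peak-level tables additionally carry `chrom`, `start`, `end` so features
#' can be joined to elements by locus.
#'
#' @param path Path to the TSV.
#' @return Data frame with at least `feature_id` and `log2fc`.
#' @export
read_differential_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("feature_id", "log2fc") %in% names(df))) {
    stop("differential table must have columns feature_id, log2fc",
         call. = FALSE)
  }
  if (any(duplicated(df$feature_id))) {
    stop("duplicated feature_id in differential table", call. = FALSE)
  }
  if (any(!is.finite(df$log2fc))) {
    stop("non-finite log2fc in differential table", call. = FALSE)
  }
  df
}

#' Write a differential table
#' @param df Differential data frame (`feature_id`, `log2fc`, optional loci).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
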