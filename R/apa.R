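# Aggregate peak analysis (APA): average the contact submatrices centered on
# loop anchor pairs and report the enrichment of the center pixel over the
# lower-left (short-distance background) corner.

#' Aggregate a contact matrix over loop anchors
#'
#' For each intra-chromosomal loop, the `(2 * flank_bins + 1)` square
#' submatrix centered at (bin of anchor1 midpoint, bin of anchor2 midpoint)
#' is extracted (anchor1 = upstream). Loops whose flanks fall off the matrix
#' or whose anchor separation is below `2 * flank_bins + 1` bins (center or
#' corner would touch the diagonal) are skipped and counted. The APA score
#' is the center cell over the mean of the `corner_size` square in the
#' lower-left corner of the aggregate (maximal row, minimal column: the
#' shorter-distance background); the z-score standardizes the center by the
#' corner's mean and standard deviation.
#'
#' @param cm A `contact_matrix`.
#' @param loops Loop data frame ([read_bedpe()]); anchors on `cm$chrom`.
#' @param flank_bins Flank half-width in bins (default 10).
#' @param corner_size Side of the background corner block (default 3).
#' @param normalize `"none"` (raw counts) or `"expected"` (observed over
#'   expected: each cell divided by the matrix's mean count at its bin
#'   offset before averaging; offsets without data fall back to the fitted
#'   power law).
#' @param decay Optional decay fit for `normalize = "expected"`.
#' @return An `apa_result`: list with `aggregate` matrix, `apa_score`,
#'   `z_score`, `n_loops_used`, `n_loops_skipped`, `flag` (notes for
#'   degenerate corners).
#' @export
aggregate_loops <- function(cm, loops, flank_bins = 10, corner_size = 3,
                            normalize = c("none", "expected"),
                            decay = NULL) {
  stopifnot(inherits(cm, "contact_matrix"))
  normalize <- match.arg(normalize)
  stopifnot(flank_bins >= 1, corner_size >= 1, corner_size <= flank_bins)
  intra <- loops[loops$chrom1 == loops$chrom2 & loops$chrom1 == cm$chrom, ,
                 drop = FALSE]
  if (nrow(intra) == 0) stop("no usable loops", call. = FALSE)
  f <- flank_bins
  size <- 2 * f + 1
  b1 <- floor((intra$start1 + intra$end1) / 2 / cm$resolution)
  b2 <- floor((intra$start2 + intra$end2) / 2 / cm$resolution)
  lo <- pmin(b1, b2)
  hi <- pmax(b1, b2)
  usable <- (lo - f) >= 0 & (hi + f) < cm$n_bins & (hi - lo) >= size
  if (!any(usable)) stop("no usable loops", call. = FALSE)
  if (normalize == "expected") {
    decay <- decay %||% fit_contact_decay(cm)
    exp_by_off <- expected_contact(decay,
                                   seq_len(cm$n_bins) * cm$resolution)
    prof <- decay$profile
    exp_by_off[prof$offset_bins[prof$mean_count > 0]] <-
      prof$mean_count[prof$mean_count > 0]
  }
  agg <- matrix(0, size, size)
  dense <- as.matrix(cm$counts)  # desk-scale matrices; simplest correct path
  for (k in which(usable)) {
    sub <- dense[(lo[k] - f):(lo[k] + f) + 1, (hi[k] - f):(hi[k] + f) + 1]
    if (normalize == "expected") {
      dist_bins <- abs(outer((lo[k] - f):(lo[k] + f),
                             (hi[k] - f):(hi[k] + f), `-`))
      sub <- sub / matrix(exp_by_off[dist_bins], size, size)
    }
    agg <- agg + sub
  }
  agg <- agg / sum(usable)
  center <- agg[f + 1, f + 1]
  corner <- agg[(size - corner_size + 1):size, 1:corner_size]
  corner_mean <- mean(corner)
  corner_sd <- stats::sd(as.numeric(corner))
  flag <- NULL
  if (corner_mean == 0) {
    apa_score <- NA_real_
    flag <- "zero corner mean; APA score undefined"
  } else {
    apa_score <- center / corner_mean
  }
  if (is.na(corner_sd) || corner_sd == 0) {
    z_score <- if (!is.na(corner_mean) && center == corner_mean) 0
    else NA_real_
    if (is.na(z_score)) flag <- c(flag, "zero corner variance")
  } else {
    z_score <- (center - corner_mean) / corner_sd
  }
  structure(list(aggregate = agg, apa_score = apa_score, z_score = z_score,
                 n_loops_used = sum(usable),
                 n_loops_skipped = nrow(intra) - sum(usable) +
                   (nrow(loops) - nrow(intra)),
                 flag = flag),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("apa_result: score %.3f, z %.3f, %d loops used (%d skipped)\n",
              x$apa_score, x$z_score, x$n_loops_used, x$n_loops_skipped))
  if (!is.null(x$flag)) cat("flag:", paste(x$flag, collapse = "; "), "\n")
  invisible(x)
}

#' Write an APA aggregate matrix as TSV
#' @param apa An `apa_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_apa_matrix <- function(apa, path) {
  utils::write.table(apa$aggregate, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
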