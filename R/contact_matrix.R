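# Binned symmetric per-chromosome contact matrices. Storage is a sparse
# symmetric Matrix; the text interchange format is tab-separated COO
# (chrom, bin1_start, bin2_start, count), upper triangle sufficient.

#' Construct a contact matrix from COO triplets
#'
#' @param chrom Chromosome name.
#' @param resolution Bin width in bp.
#' @param bin1,bin2 Integer bin indices (0-based).
#' @param count Non-negative counts; duplicate (i, j) entries are summed,
#'   and (i, j) / (j, i) duplicates count once each.
#' @param n_bins Number of bins; defaults to `max(bin1, bin2) + 1`.
#' @param normalization Free-text note on how counts were normalized
#'   upstream ("raw", "balanced", ...); recorded, not interpreted.
#'
#' @return A `contact_matrix` object: list with `chrom`, `resolution`,
#'   `n_bins`, `counts` (symmetric sparse matrix) and `normalization`.
#' @export
contact_matrix <- function(chrom, resolution, bin1, bin2, count,
                           n_bins = NULL, normalization = "unknown") {
  stopifnot(length(chrom) == 1, resolution > 0)
  if (length(bin1) != length(bin2) || length(bin1) != length(count)) {
    stop("bin1, bin2 and count must have equal length", call. = FALSE)
  }
  if (any(count < 0)) stop("negative contact count", call. = FALSE)
  if (any(bin1 < 0 | bin2 < 0)) stop("negative bin index", call. = FALSE)
  i <- pmin(bin1, bin2)
  j <- pmax(bin1, bin2)
  if (is.null(n_bins)) n_bins <- if (length(j)) max(j) + 1 else 1L
  n_bins <- as.integer(n_bins)
  if (length(j) && max(j) >= n_bins) {
    stop("bin index beyond n_bins", call. = FALSE)
  }
  counts <- Matrix::sparseMatrix(i = i + 1, j = j + 1, x = as.numeric(count),
                                 dims = c(n_bins, n_bins), symmetric = TRUE)
  structure(list(chrom = as.character(chrom),
                 resolution = as.numeric(resolution),
                 n_bins = n_bins, counts = counts,
                 normalization = normalization),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins @ %s bp, %d stored cells (%s)\n",
              x$chrom, x$n_bins, fmt_pos(x$resolution),
              length(x$counts@x), x$normalization))
  invisible(x)
}

#' Build a contact matrix from a dense symmetric matrix
#'
#' Convenience constructor used for toy examples and tests.
#'
#' @param mat Square symmetric numeric matrix of binned counts.
#' @inheritParams contact_matrix
#' @return A `contact_matrix`.
#' @export
contact_matrix_from_dense <- function(mat, chrom = "chr1",
                                      resolution = 10000,
                                      normalization = "unknown") {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (!isSymmetric(unname(mat))) stop("matrix must be symmetric", call. = FALSE)
  idx <- which(mat != 0 & upper.tri(mat, diag = TRUE), arr.ind = TRUE)
  contact_matrix(chrom, resolution,
                 bin1 = idx[, 1] - 1, bin2 = idx[, 2] - 1,
                 count = mat[idx], n_bins = nrow(mat),
                 normalization = normalization)
}

#' Read a contact matrix from COO text
#'
#' Tab-separated columns: chrom, bin1_start, bin2_start, count. Bin starts
#' must be multiples of `resolution`; duplicate entries are summed; entries
#' absent from the file are 0. The upper triangle is sufficient.
#'
#' @param path Path to the COO file.
#' @param resolution Bin width in bp.
#' @param n_bins Optional number of bins (e.g. chromosome length /
#'   resolution); inferred from the data when `NULL`.
#' @param normalization Note recorded on the object (see [contact_matrix()]).
#' @return A `contact_matrix`.
#' @export
read_contact_matrix <- function(path, resolution, n_bins = NULL,
                                normalization = "unknown") {
  lines <- read_data_lines(path)
  if (length(lines) == 0) {
    return(contact_matrix("chr?", resolution, integer(), integer(),
                          numeric(), n_bins = n_bins %||% 1L,
                          normalization = normalization))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 4L)) {
    stop(sprintf("malformed COO line %d in %s: %d columns (expected 4)",
                 which(ncols != 4L)[1], path, ncols[which(ncols != 4L)[1]]),
         call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  if (length(unique(chrom)) > 1) {
    stop("contact COO file must hold a single chromosome; found: ",
         paste(unique(chrom), collapse = ", "), call. = FALSE)
  }
  s1 <- as.numeric(vapply(fields, `[[`, "", 2L))
  s2 <- as.numeric(vapply(fields, `[[`, "", 3L))
  count <- as.numeric(vapply(fields, `[[`, "", 4L))
  if (anyNA(s1) || anyNA(s2) || anyNA(count)) {
    stop("non-numeric field in COO file ", path, call. = FALSE)
  }
  if (any(count < 0)) stop("negative count in COO file ", path, call. = FALSE)
  if (any(s1 %% resolution != 0 | s2 %% resolution != 0)) {
    stop("bin start not a multiple of resolution in ", path, call. = FALSE)
  }
  contact_matrix(chrom[1], resolution, s1 / resolution, s2 / resolution,
                 count, n_bins = n_bins, normalization = normalization)
}

#' Write a contact matrix as COO text
#'
#' Upper-triangle entries only, sorted by (bin1, bin2).
#'
#' @param cm A `contact_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "contact_matrix"))
  trip <- contact_triplets(cm)
  ord <- order(trip$i, trip$j)
  trip <- trip[ord, , drop = FALSE]
  out <- paste(cm$chrom, fmt_pos(trip$i * cm$resolution),
               fmt_pos(trip$j * cm$resolution), trip$x, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

# upper-triangle triplets (0-based bins) of a contact_matrix
contact_triplets <- function(cm) {
  tg <- methods::as(cm$counts, "TsparseMatrix")
  keep <- tg@i <= tg@j
  data.frame(i = tg@i[keep], j = tg@j[keep], x = tg@x[keep])
}

# counts for vectors of 0-based bin pairs
contact_lookup <- function(cm, bin1, bin2) {
  n <- length(bin1)
  if (n == 0) return(numeric())
  if (any(bin1 < 0 | bin2 < 0 | bin1 >= cm$n_bins | bin2 >= cm$n_bins)) {
    bad <- which(bin1 < 0 | bin2 < 0 | bin1 >= cm$n_bins | bin2 >= cm$n_bins)[1]
    stop(sprintf("bin pair (%d, %d) outside contact matrix (%d bins)",
                 bin1[bad], bin2[bad], cm$n_bins), call. = FALSE)
  }
  cm$counts[cbind(bin1 + 1, bin2 + 1)]
}

coord_to_bin <- function(cm, pos) {
  bin <- floor(pos / cm$resolution)
  if (any(bin < 0 | bin >= cm$n_bins)) {
    bad <- which(bin < 0 | bin >= cm$n_bins)[1]
    stop(sprintf("position %s maps to bin %d outside the matrix (%d bins)",
                 fmt_pos(pos[bad]), bin[bad], cm$n_bins), call. = FALSE)
  }
  bin
}

#' Fit the distance-decay curve of a contact matrix
#'
#' Mean counts per bin offset are regressed on distance in log-log space,
#' giving the power law `expected(d) = k * d^(-alpha)` used for contact
#' pseudocounts and for expected-normalized APA.
#'
#' @param cm A `contact_matrix`.
#' @param max_offset_bins Largest bin offset entering the fit (default: all).
#' @return List with `k`, `alpha`, and the per-offset mean profile.
#' @export
fit_contact_decay <- function(cm, max_offset_bins = NULL) {
  trip <- contact_triplets(cm)
  off <- trip$j - trip$i
  max_off <- max_offset_bins %||% (cm$n_bins - 1)
  keep <- off >= 1 & off <= max_off
  if (!any(keep)) stop("no off-diagonal contacts to fit", call. = FALSE)
  sums <- tapply(trip$x[keep], off[keep], sum)
  d_bins <- as.integer(names(sums))
  # zero cells at each offset contribute to the mean
  means <- as.numeric(sums) / (cm$n_bins - d_bins)
  use <- means > 0
  if (sum(use) < 2) stop("not enough distance points to fit decay", call. = FALSE)
  d_bp <- d_bins[use] * cm$resolution
  fit <- stats::lm(log(means[use]) ~ log(d_bp))
  alpha <- -unname(stats::coef(fit)[2])
  k <- exp(unname(stats::coef(fit)[1]))
  list(k = k, alpha = alpha,
       profile = data.frame(offset_bins = d_bins, mean_count = means))
}

#' Expected contact at a genomic distance under a fitted decay
#' @param decay Fit from [fit_contact_decay()].
#' @param distance_bp Distance(s) in bp; distances below one bin are clamped
#'   to the resolution implied by the fit profile.
#' @return Expected count(s).
#' @export
expected_contact <- function(decay, distance_bp) {
  d <- pmax(distance_bp, 1)
  decay$k * d^(-decay$alpha)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
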