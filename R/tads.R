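# Directionality-index TAD calling. For each bin the index contrasts the
# summed upstream contacts A against the downstream contacts B within a
# fixed window: DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E) with
# E = (A + B) / 2. Strongly negative runs (upstream bias, domain end)
# followed by strongly positive runs (downstream bias, domain start) mark
# boundaries.

#' Directionality index track of a contact matrix
#'
#' @param cm A `contact_matrix`.
#' @param window Reach of the upstream/downstream sums in bp (default 2 Mb).
#'   Must cover at least 2 bins and no more than half the chromosome.
#' @return A `di_track`: list with `chrom`, `resolution`, `window_bins` and
#'   `di`, a per-bin vector with `NA` at bins lacking full window coverage.
#' @export
directionality_index <- function(cm, window = 2e6) {
  stopifnot(inherits(cm, "contact_matrix"))
  w <- floor(window / cm$resolution)
  if (w < 2) stop("window must cover at least 2 bins", call. = FALSE)
  if (w > cm$n_bins / 2) {
    stop("window exceeds half the chromosome", call. = FALSE)
  }
  trip <- contact_triplets(cm)
  off <- trip$j - trip$i
  A <- rep(0, cm$n_bins)
  B <- rep(0, cm$n_bins)
  # accumulate one offset at a time, adding the same stored values to the
  # downstream sum of bin i and the upstream sum of bin j: on a
  # translation-invariant matrix A and B then agree exactly, so DI is 0
  # with no floating-point residue
  by_off <- split(seq_along(off), off)
  for (d in seq_len(w)) {
    idx <- by_off[[as.character(d)]]
    if (is.null(idx)) next
    B_add <- rowsum(trip$x[idx], trip$i[idx])
    B[as.integer(rownames(B_add)) + 1] <-
      B[as.integer(rownames(B_add)) + 1] + B_add[, 1]
    A_add <- rowsum(trip$x[idx], trip$j[idx])
    A[as.integer(rownames(A_add)) + 1] <-
      A[as.integer(rownames(A_add)) + 1] + A_add[, 1]
  }
  E <- (A + B) / 2
  di <- ifelse(E == 0 | A == B, 0,
               sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E))
  mask <- seq_len(cm$n_bins) - 1
  di[mask < w | mask >= cm$n_bins - w] <- NA_real_
  structure(list(chrom = cm$chrom, resolution = cm$resolution,
                 window_bins = w, di = di),
            class = "di_track")
}

#' @export
print.di_track <- function(x, ...) {
  cat(sprintf("di_track: %s, %d bins @ %s bp, window %d bins\n",
              x$chrom, length(x$di), fmt_pos(x$resolution), x$window_bins))
  invisible(x)
}

#' Write a DI track as bedGraph
#' @param track A `di_track`.
#' @param path Output path; masked bins are omitted.
#' @return `path`, invisibly.
#' @export
write_di_bedgraph <- function(track, path) {
  keep <- which(!is.na(track$di))
  out <- paste(track$chrom, fmt_pos((keep - 1) * track$resolution),
               fmt_pos(keep * track$resolution), track$di[keep], sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Call TADs from a directionality index track
#'
#' Boundaries sit at sign transitions where a negative DI run ends and a
#' positive run starts, provided both flanking runs reach the magnitude
#' threshold (the `magnitude_quantile` of |DI| over covered bins). TADs are
#' the intervals between successive boundaries (and the chromosome ends),
#' filtered by `min_tad_size`.
#'
#' @param track A `di_track`.
#' @param magnitude_quantile Quantile of |DI| that both flanking runs must
#'   attain (default 0.8).
#' @param min_tad_size Minimum TAD width in bp (default 100 kb).
#' @return Data frame of TADs (`chrom`, `start`, `end`), non-overlapping and
#'   sorted. An all-zero track yields a single chromosome-spanning TAD with
#'   a warning.
#' @export
call_tads <- function(track, magnitude_quantile = 0.8, min_tad_size = 1e5) {
  stopifnot(inherits(track, "di_track"))
  di <- track$di
  n <- length(di)
  chrom_end <- n * track$resolution
  covered <- which(!is.na(di))
  if (length(covered) == 0 || all(di[covered] == 0)) {
    warning("directionality index carries no signal; returning one TAD",
            call. = FALSE)
    return(data.frame(chrom = track$chrom, start = 0, end = chrom_end,
                      stringsAsFactors = FALSE))
  }
  threshold <- stats::quantile(abs(di[covered]), magnitude_quantile,
                               names = FALSE)
  sgn <- sign(di[covered])
  nz <- which(sgn != 0)
  boundaries <- numeric(0)
  if (length(nz) >= 2) {
    runs <- rle(sgn[nz])
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths + 1
    for (r in seq_len(length(runs$values) - 1)) {
      if (runs$values[r] == -1 && runs$values[r + 1] == 1) {
        neg_bins <- covered[nz[run_start[r]:run_end[r]]]
        pos_bins <- covered[nz[run_start[r + 1]:run_end[r + 1]]]
        if (max(abs(di[neg_bins])) >= threshold &&
            max(abs(di[pos_bins])) >= threshold) {
          # boundary at the first bin of the positive (domain-start) run
          boundaries <- c(boundaries, (pos_bins[1] - 1) * track$resolution)
        }
      }
    }
  }
  edges <- unique(c(0, boundaries, chrom_end))
  tads <- data.frame(chrom = track$chrom,
                     start = utils::head(edges, -1),
                     end = utils::tail(edges, -1),
                     stringsAsFactors = FALSE)
  tads <- tads[tads$end - tads$start >= min_tad_size, , drop = FALSE]
  rownames(tads) <- NULL
  tads
}

#' Classify hubs by the number of TADs they touch
#'
#' Counts, per hub, the distinct TADs overlapped by any member (elements by
#' interval, genes by TSS). Hubs touching exactly one TAD are `within_one`,
#' two or more `spans_multiple`, none `outside` (all members fall in
#' inter-TAD gaps).
#'
#' @param crhs A `crh_set`.
#' @param tads TAD data frame ([call_tads()]); must be non-overlapping.
#' @return List with `per_hub` (data frame `hub_id`, `n_tads`, `class`) and
#'   `fractions` (named: `within_one`, `spans_multiple`, `outside`).
#' @export
classify_crh_tads <- function(crhs, tads) {
  if (nrow(tads) > 1) {
    tads <- sort_intervals(tads)
    same <- tads$chrom[-nrow(tads)] == tads$chrom[-1]
    if (any(same & tads$end[-nrow(tads)] > tads$start[-1][same])) {
      stop("TADs overlap", call. = FALSE)
    }
  }
  mem <- crhs$membership
  hub_ids <- unique(mem$hub_id)
  hits <- overlap_pairs(mem, tads)
  n_tads <- vapply(hub_ids, function(h) {
    rows <- hits[mem$hub_id[hits$query] == h, , drop = FALSE]
    length(unique(rows$subject))
  }, integer(1))
  cls <- ifelse(n_tads == 0, "outside",
                ifelse(n_tads == 1, "within_one", "spans_multiple"))
  per_hub <- data.frame(hub_id = hub_ids, n_tads = unname(n_tads),
                        class = unname(cls), stringsAsFactors = FALSE)
  fr <- table(factor(per_hub$class,
                     levels = c("within_one", "spans_multiple", "outside")))
  fractions <- if (nrow(per_hub))
    stats::setNames(as.numeric(fr) / nrow(per_hub), names(fr))
  else stats::setNames(rep(NA_real_, 3), names(fr))
  list(per_hub = per_hub, fractions = fractions)
}
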