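# Activity-by-contact (ABC) scoring. A candidate element's score for a gene
# is its activity (geometric mean of ATAC and H3K27ac signal) times its 3D
# contact with the gene's TSS, normalized by the summed activity x contact of
# every candidate in a window around the gene, so per-gene scores sum to 1.

#' Define candidate regulatory elements from ATAC and H3K27ac peaks
#'
#' Takes the union of the two peak sets ("and/or" rule), merges overlapping
#' intervals, pads or clips each merged interval around its midpoint into
#' `[min_width, max_width]`, and flags (without removing) candidates that
#' overlap a promoter window.
#'
#' @param atac,h3k27ac Peak data frames ([read_narrowpeak()]).
#' @param promoters Interval data frame of promoter windows, typically
#'   [promoter_windows()] on a gene table. May be `NULL` (no flagging).
#' @param min_width,max_width Candidate width bounds in bp.
#'
#' @return Data frame with `element_id`, `chrom`, `start`, `end`,
#'   `promoter_proximal` (logical), sorted by (chrom, start); element ids are
#'   assigned in that order.
#' @export
define_candidates <- function(atac, h3k27ac, promoters = NULL,
                              min_width = 500, max_width = 10000) {
  stopifnot(min_width > 0, max_width >= min_width)
  pool <- rbind(atac[c("chrom", "start", "end")],
                h3k27ac[c("chrom", "start", "end")])
  if (nrow(pool) == 0) stop("no candidate elements", call. = FALSE)
  check_chrom_compat(atac$chrom, h3k27ac$chrom, "ATAC peaks", "H3K27ac peaks")
  merged <- GenomicRanges::reduce(as_granges(pool))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                   start = GenomicRanges::start(merged) - 1,
                   end = GenomicRanges::end(merged),
                   stringsAsFactors = FALSE)
  mid <- interval_midpoint(df)
  width <- df$end - df$start
  width <- pmin(pmax(width, min_width), max_width)
  df$start <- pmax(0, mid - floor(width / 2))
  df$end <- df$start + width
  df <- sort_intervals(df)
  df$element_id <- sprintf("el_%05d", seq_len(nrow(df)))
  df$promoter_proximal <- FALSE
  if (!is.null(promoters) && nrow(promoters) > 0) {
    hits <- overlap_pairs(df, promoters)
    df$promoter_proximal[unique(hits$query)] <- TRUE
  }
  df[c("element_id", "chrom", "start", "end", "promoter_proximal")]
}

#' Promoter windows around gene TSSs
#' @param genes Gene data frame ([read_gene_table()]).
#' @param margin Half-width in bp around the TSS (default 500).
#' @return Interval data frame with a `gene_id` column.
#' @export
promoter_windows <- function(genes, margin = 500) {
  df <- data.frame(chrom = genes$chrom,
                   start = pmax(0, genes$tss - margin),
                   end = genes$tss + margin,
                   gene_id = genes$gene_id,
                   stringsAsFactors = FALSE)
  sort_intervals(df)
}

#' Compute element activities
#'
#' The activity is the geometric mean of the two assay signals over each
#' element, `A = sqrt((atac + eps) * (k27 + eps))`. A peak's signal is spread
#' uniformly over its width, so a peak overlapping an element contributes
#' `signalValue * overlap / peak_width`.
#'
#' @param elements Candidate table from [define_candidates()].
#' @param atac,h3k27ac Peak data frames with `signal`.
#' @param pseudocount Added to each assay signal before the geometric mean
#'   (default 0.1) so elements supported by a single assay keep a nonzero
#'   activity.
#' @return `elements` with an added `activity` column (plus `atac_signal`,
#'   `k27_signal`).
#' @export
compute_activity <- function(elements, atac, h3k27ac, pseudocount = 0.1) {
  if (any(atac$signal < 0) || any(h3k27ac$signal < 0)) {
    stop("negative peak signal", call. = FALSE)
  }
  elements$atac_signal <- assay_signal(elements, atac)
  elements$k27_signal <- assay_signal(elements, h3k27ac)
  elements$activity <- sqrt((elements$atac_signal + pseudocount) *
                              (elements$k27_signal + pseudocount))
  elements
}

assay_signal <- function(elements, peaks) {
  sig <- rep(0, nrow(elements))
  if (nrow(peaks) == 0) return(sig)
  hits <- overlap_pairs(elements, peaks)
  if (nrow(hits) == 0) return(sig)
  peak_width <- peaks$end[hits$subject] - peaks$start[hits$subject]
  contrib <- peaks$signal[hits$subject] * hits$width / peak_width
  agg <- tapply(contrib, hits$query, sum)
  sig[as.integer(names(agg))] <- as.numeric(agg)
  sig
}

#' Contact between an element and a gene TSS
#'
#' Looks up the count for the (element midpoint bin, TSS bin) pair and adds a
#' distance-dependent pseudocount: a fixed fraction of the matrix's own
#' fitted power-law expectation at that distance, so zero-count pairs never
#' score exactly zero.
#'
#' @param cm A `contact_matrix`.
#' @param element_mid,tss Vectors of element midpoints and TSS positions (bp).
#' @param decay Decay fit from [fit_contact_decay()]; computed from `cm` when
#'   `NULL`.
#' @param pseudocount_frac Fraction of the expected contact used as
#'   pseudocount (default 0.01).
#' @return Numeric vector of contact values (> 0).
#' @export
extract_contact <- function(cm, element_mid, tss, decay = NULL,
                            pseudocount_frac = 0.01) {
  decay <- decay %||% fit_contact_decay(cm)
  b1 <- coord_to_bin(cm, element_mid)
  b2 <- coord_to_bin(cm, tss)
  raw <- contact_lookup(cm, b1, b2)
  d_eff <- pmax(abs(element_mid - tss), cm$resolution)
  raw + pseudocount_frac * expected_contact(decay, d_eff)
}

#' Compute ABC scores for all element-gene pairs in a window
#'
#' For each expressed gene, every distal candidate whose midpoint lies within
#' `window / 2` of the TSS is scored as
#' `ABC(E, G) = A_E * C_EG / sum_e A_e * C_eG`, the sum running over all
#' candidates in the gene's window, so pre-threshold scores per gene sum to 1.
#'
#' @param elements Candidates with activities ([compute_activity()]).
#' @param genes Gene data frame.
#' @param cm A `contact_matrix` for the chromosome under analysis.
#' @param window Total window width in bp centered on the TSS (default 5 Mb).
#' @param expression_floor Genes at or below this expression are skipped
#'   (default 0.5).
#' @param include_promoter_proximal Keep candidates flagged
#'   promoter-proximal (default `FALSE`).
#' @param per_element_norm If `TRUE`, normalize over the window centered on
#'   each element instead of on the gene (comparison mode; scores no longer
#'   sum to 1 per gene).
#' @param decay,pseudocount_frac Passed to [extract_contact()].
#'
#' @return Data frame of pairs: `element_id`, `chrom`, `start`, `end`,
#'   `gene_id`, `tss`, `distance`, `activity`, `contact`, `abc_score`.
#' @export
compute_abc_scores <- function(elements, genes, cm, window = 5e6,
                               expression_floor = 0.5,
                               include_promoter_proximal = FALSE,
                               per_element_norm = FALSE,
                               decay = NULL, pseudocount_frac = 0.01) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (!"activity" %in% names(elements)) {
    stop("elements must carry activities; run compute_activity() first",
         call. = FALSE)
  }
  check_chrom_compat(elements$chrom, genes$chrom, "elements", "genes")
  el <- elements[elements$chrom == cm$chrom, , drop = FALSE]
  if (!include_promoter_proximal && "promoter_proximal" %in% names(el)) {
    el <- el[!el$promoter_proximal, , drop = FALSE]
  }
  gn <- genes[genes$chrom == cm$chrom & genes$expression > expression_floor, ,
              drop = FALSE]
  empty <- data.frame(element_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      gene_id = character(), tss = numeric(),
                      distance = numeric(), activity = numeric(),
                      contact = numeric(), abc_score = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(el) == 0 || nrow(gn) == 0) return(empty)

  decay <- decay %||% fit_contact_decay(cm)
  mid <- interval_midpoint(el)
  radius <- window / 2
  # cross join restricted to |mid - tss| <= radius
  ord <- order(mid)
  el <- el[ord, , drop = FALSE]
  mid <- mid[ord]
  lo <- findInterval(gn$tss - radius, mid, left.open = TRUE) + 1
  hi <- findInterval(gn$tss + radius, mid)
  n_each <- pmax(0L, hi - lo + 1L)
  skipped <- gn$gene_id[n_each == 0L]
  if (length(skipped)) {
    warning("no candidate elements in window for gene(s): ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "", call. = FALSE)
  }
  gi <- rep(seq_len(nrow(gn)), n_each)
  ei <- unlist(lapply(which(n_each > 0L),
                      function(g) seq(lo[g], hi[g])), use.names = FALSE)
  if (length(gi) == 0) return(empty)

  contact <- extract_contact(cm, mid[ei], gn$tss[gi], decay = decay,
                             pseudocount_frac = pseudocount_frac)
  weight <- el$activity[ei] * contact
  if (per_element_norm) {
    denom_tab <- vapply(seq_len(nrow(el)), function(e) {
      within <- abs(gn$tss - mid[e]) <= radius
      if (!any(within)) return(NA_real_)
      sum(el$activity[e] * extract_contact(cm, rep(mid[e], sum(within)),
                                           gn$tss[within], decay = decay,
                                           pseudocount_frac = pseudocount_frac))
    }, numeric(1))
    denom <- denom_tab[ei]
  } else {
    sums <- tapply(weight, gi, sum)
    denom <- as.numeric(sums)[match(gi, as.integer(names(sums)))]
  }
  pairs <- data.frame(element_id = el$element_id[ei],
                      chrom = el$chrom[ei],
                      start = el$start[ei], end = el$end[ei],
                      gene_id = gn$gene_id[gi], tss = gn$tss[gi],
                      distance = abs(mid[ei] - gn$tss[gi]),
                      activity = el$activity[ei],
                      contact = contact,
                      abc_score = weight / denom,
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene_id, -pairs$abc_score, pairs$element_id), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Threshold ABC pairs into the enhancer-gene pair set
#'
#' @param pairs Pair table from [compute_abc_scores()].
#' @param cutoff Minimum ABC score, strictly inside (0, 1); default 0.01.
#' @return Pairs with `abc_score >= cutoff`; attributes `n_elements` and
#'   `n_genes` hold the distinct surviving element and gene counts.
#' @export
threshold_pairs <- function(pairs, cutoff = 0.01) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 ||
      cutoff <= 0 || cutoff >= 1) {
    stop("cutoff must lie strictly inside (0, 1)", call. = FALSE)
  }
  keep <- pairs[pairs$abc_score >= cutoff, , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "n_elements") <- length(unique(keep$element_id))
  attr(keep, "n_genes") <- length(unique(keep$gene_id))
  keep
}

#' Distance statistics for top and bottom score bands
#'
#' Ranks pairs by ABC score and summarizes element-TSS distances within the
#' top and bottom `quantile_band` fractions (e.g. the top and bottom 1%).
#'
#' @param pairs Pair table with `abc_score` and `distance`.
#' @param quantile_band Band width as a fraction in (0, 0.5].
#' @return List with `n_band` and per-band `mean` / `median` distances.
#' @export
pair_distance_stats <- function(pairs, quantile_band = 0.01) {
  stopifnot(quantile_band > 0, quantile_band <= 0.5)
  n <- nrow(pairs)
  if (n < 1 / quantile_band) {
    stop(sprintf("need at least %d pairs for a %.3g band",
                 ceiling(1 / quantile_band), quantile_band), call. = FALSE)
  }
  ord <- order(-pairs$abc_score, pairs$element_id, pairs$gene_id)
  n_band <- max(1L, floor(n * quantile_band))
  top <- pairs$distance[ord[seq_len(n_band)]]
  bottom <- pairs$distance[ord[seq(n - n_band + 1, n)]]
  list(n_band = n_band,
       top = list(mean = mean(top), median = stats::median(top)),
       bottom = list(mean = mean(bottom), median = stats::median(bottom)))
}
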