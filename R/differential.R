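# Condition-induced changes: correlate gene-expression log2 fold changes
# with the log2 fold changes of linked enhancers, per E-G pair and per hub.

#' Naive log2 fold change between two count vectors
#'
#' `log2fc = log2((b + pseudocount) / (a + pseudocount))`; intended for
#' synthetic data (real differential tables come from dedicated tools and
#' are consumed via [read_differential_table()]).
#'
#' @param counts_a,counts_b Named non-negative numeric vectors over a shared
#'   feature namespace.
#' @param pseudocount Added to both sides (default 1).
#' @return Data frame `feature_id`, `log2fc`.
#' @export
compute_log2fc <- function(counts_a, counts_b, pseudocount = 1) {
  if (any(counts_a < 0) || any(counts_b < 0)) {
    stop("negative counts", call. = FALSE)
  }
  ids <- union(names(counts_a), names(counts_b))
  if (is.null(ids)) stop("count vectors must be named", call. = FALSE)
  a <- counts_a[ids]; a[is.na(a)] <- 0
  b <- counts_b[ids]; b[is.na(b)] <- 0
  data.frame(feature_id = ids,
             log2fc = log2((b + pseudocount) / (a + pseudocount)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# join element loci to a peak-level differential table by maximal overlap;
# returns log2fc per element row (NA when unmatched)
match_lfc_by_locus <- function(elements, enh_lfc) {
  need <- c("feature_id", "chrom", "start", "end", "log2fc")
  if (!all(need %in% names(enh_lfc))) {
    stop("enhancer differential table needs columns ",
         paste(need, collapse = ", "), " for locus matching", call. = FALSE)
  }
  out <- rep(NA_real_, nrow(elements))
  hits <- overlap_pairs(elements, enh_lfc)
  if (nrow(hits)) {
    hits <- hits[order(hits$query, -hits$width, hits$subject), , drop = FALSE]
    best <- hits[!duplicated(hits$query), , drop = FALSE]
    out[best$query] <- enh_lfc$log2fc[best$subject]
  }
  out
}

#' Correlation of expression and enhancer-signal changes over E-G pairs
#'
#' One observation per thresholded pair: the gene's log2 fold change (by id)
#' against its linked enhancer's (matched by maximal locus overlap with the
#' differential peak table). Optionally restricted to observations where
#' both |log2fc| reach `min_abs_lfc`.
#'
#' @param pairs Thresholded pair table with element loci.
#' @param gene_lfc Differential table with `feature_id` = gene ids.
#' @param enh_lfc Differential table with peak loci (`chrom`,`start`,`end`).
#' @param min_abs_lfc Drop observations where either |log2fc| is below this
#'   (default 0 = keep all).
#' @return List: `r` (Pearson), `n`, `p` (two-sided, t transform),
#'   `n_unmatched` (pairs without gene or enhancer fold change).
#' @export
eg_change_correlation <- function(pairs, gene_lfc, enh_lfc,
                                  min_abs_lfc = 0) {
  g <- gene_lfc$log2fc[match(pairs$gene_id, gene_lfc$feature_id)]
  e <- match_lfc_by_locus(pairs, enh_lfc)
  ok <- !is.na(g) & !is.na(e)
  n_unmatched <- sum(!ok)
  g <- g[ok]; e <- e[ok]
  if (min_abs_lfc > 0) {
    keep <- abs(g) >= min_abs_lfc & abs(e) >= min_abs_lfc
    g <- g[keep]; e <- e[keep]
  }
  pearson_with_p(g, e, n_unmatched = n_unmatched)
}

pearson_with_p <- function(x, y, n_unmatched = 0) {
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), n = n, p = ct$p.value,
       n_unmatched = n_unmatched)
}

#' Hub-level co-regulation of genes and enhancers
#'
#' Observations are all gene x enhancer combinations co-resident in the same
#' hub (by default including combinations not directly linked by an edge,
#' reflecting shared hub-level regulation); `direct_only = TRUE` restricts
#' to edges.
#'
#' @param crhs A `crh_set`.
#' @param gene_lfc,enh_lfc Differential tables as in
#'   [eg_change_correlation()].
#' @param direct_only Use only directly linked pairs (default `FALSE`).
#' @return List: `r`, `n`, `p`, `n_unmatched`.
#' @export
hub_coregulation <- function(crhs, gene_lfc, enh_lfc, direct_only = FALSE) {
  mem <- crhs$membership
  el <- mem[mem$member_type == "element", , drop = FALSE]
  el$lfc <- match_lfc_by_locus(el, enh_lfc)
  gn <- mem[mem$member_type == "gene", , drop = FALSE]
  gn$lfc <- gene_lfc$log2fc[match(gn$member_id, gene_lfc$feature_id)]
  if (direct_only) {
    combos <- crhs$edges
  } else {
    combos <- merge(gn[c("hub_id", "member_id")],
                    el[c("hub_id", "member_id")],
                    by = "hub_id", suffixes = c("_gene", "_el"))
    names(combos)[names(combos) == "member_id_gene"] <- "gene_id"
    names(combos)[names(combos) == "member_id_el"] <- "element_id"
  }
  if (nrow(combos) == 0) stop("no co-resident combinations", call. = FALSE)
  g <- gn$lfc[match(combos$gene_id, gn$member_id)]
  e <- el$lfc[match(combos$element_id, el$member_id)]
  ok <- !is.na(g) & !is.na(e)
  pearson_with_p(g[ok], e[ok], n_unmatched = sum(!ok))
}

#' Top genes by expression
#'
#' Deterministic ranking by descending expression with ties broken by
#' gene id (lexicographic).
#'
#' @param genes Gene data frame.
#' @param k Number of genes to return (default 50).
#' @return Character vector of `k` gene ids.
#' @export
rank_genes_by_expression <- function(genes, k = 50) {
  if (k > nrow(genes)) stop("k exceeds the number of genes", call. = FALSE)
  genes$gene_id[order(-genes$expression, genes$gene_id)][seq_len(k)]
}

#' Hub sizes for hubs containing versus lacking a gene set
#'
#' Splits hubs by whether they contain any gene of `gene_set` and compares
#' the member-count distributions with a two-sided Wilcoxon rank-sum test
#' (normal approximation with tie correction, no continuity correction).
#'
#' @param crhs A `crh_set`.
#' @param gene_set Character vector of gene ids.
#' @return List: `sizes_in`, `sizes_out`, `z` (standardized rank-sum
#'   statistic, positive when set-containing hubs are larger), `p`.
#' @export
hub_size_by_gene_set <- function(crhs, gene_set) {
  mem <- crhs$membership
  sizes <- hub_sizes(crhs)
  has_gene <- unique(mem$hub_id[mem$member_type == "gene" &
                                  mem$member_id %in% gene_set])
  x <- as.numeric(sizes[names(sizes) %in% has_gene])
  y <- as.numeric(sizes[!names(sizes) %in% has_gene])
  if (length(x) == 0 || length(y) == 0) {
    stop("both hub groups must be non-empty", call. = FALSE)
  }
  z <- rank_sum_z(x, y)
  list(sizes_in = x, sizes_out = y, z = z, p = 2 * stats::pnorm(-abs(z)))
}

# standardized Mann-Whitney statistic with tie correction
rank_sum_z <- function(x, y) {
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  ties <- table(r)
  sigma2 <- (nx * ny / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 == 0) return(0)
  (W - mu) / sqrt(sigma2)
}
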