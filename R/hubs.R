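# Cis-regulatory hubs (CRHs): connected components of the bipartite graph
# whose two node classes are gene promoters and distal elements and whose
# edges are thresholded ABC pairs. A "crh_set" is a list with a membership
# table (hub_id, member_type, member_id, chrom, start, end) and an edge
# table (hub_id, element_id, gene_id).

#' Build cis-regulatory hubs from thresholded pairs
#'
#' Each hub is one connected component of the bipartite element/gene graph.
#' Hubs are ordered by descending member count with ties broken by leftmost
#' coordinate, and assigned deterministic ids in that order.
#'
#' @param pairs Thresholded pair table ([threshold_pairs()]); must carry
#'   element loci (`chrom`, `start`, `end`) and gene `tss`.
#' @return A `crh_set`: list with `membership` and `edges` data frames.
#' @export
build_crhs <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(structure(list(
      membership = data.frame(hub_id = character(), member_type = character(),
                              member_id = character(), chrom = character(),
                              start = numeric(), end = numeric(),
                              stringsAsFactors = FALSE),
      edges = data.frame(hub_id = character(), element_id = character(),
                         gene_id = character(), stringsAsFactors = FALSE)),
      class = "crh_set"))
  }
  if (length(intersect(unique(pairs$element_id), unique(pairs$gene_id)))) {
    stop("element and gene id namespaces collide", call. = FALSE)
  }
  dup <- duplicated(pairs[c("element_id", "gene_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) removed", call. = FALSE)
    pairs <- pairs[!dup, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    pairs[c("element_id", "gene_id")], directed = FALSE)
  comp <- igraph::components(g)
  node <- names(comp$membership)
  comp_of_edge <- comp$membership[pairs$element_id]

  # member coordinate table (elements: interval; genes: TSS point)
  el <- unique(pairs[c("element_id", "chrom", "start", "end")])
  gn <- unique(pairs[c("gene_id", "chrom", "tss")])
  members <- rbind(
    data.frame(member_type = "element", member_id = el$element_id,
               chrom = el$chrom, start = el$start, end = el$end,
               stringsAsFactors = FALSE),
    data.frame(member_type = "gene", member_id = gn$gene_id,
               chrom = gn$chrom, start = gn$tss, end = gn$tss + 1,
               stringsAsFactors = FALSE))
  members$comp <- comp$membership[members$member_id]

  # deterministic hub order: descending size, then leftmost member
  size <- tapply(members$member_id, members$comp, length)
  leftmost <- tapply(members$start, members$comp, min)
  chrom1 <- tapply(members$chrom, members$comp, min)
  comp_ids <- as.integer(names(size))
  ord <- order(-as.numeric(size), as.character(chrom1), as.numeric(leftmost),
               comp_ids)
  hub_of_comp <- stats::setNames(sprintf("hub_%05d", seq_along(ord)),
                                 comp_ids[ord])
  members$hub_id <- hub_of_comp[as.character(members$comp)]
  members <- members[order(members$hub_id, members$member_type,
                           members$chrom, members$start), ,
                     drop = FALSE]
  membership <- members[c("hub_id", "member_type", "member_id",
                          "chrom", "start", "end")]
  rownames(membership) <- NULL
  edges <- data.frame(hub_id = hub_of_comp[as.character(comp_of_edge)],
                      element_id = pairs$element_id,
                      gene_id = pairs$gene_id, stringsAsFactors = FALSE)
  edges <- edges[order(edges$hub_id, edges$element_id, edges$gene_id), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(membership = membership, edges = edges), class = "crh_set")
}

#' @export
print.crh_set <- function(x, ...) {
  cat(sprintf("crh_set: %d hubs, %d members, %d edges\n",
              length(unique(x$membership$hub_id)), nrow(x$membership),
              nrow(x$edges)))
  invisible(x)
}

n_hubs <- function(crhs) length(unique(crhs$membership$hub_id))

hub_sizes <- function(crhs) {
  tab <- table(crhs$membership$hub_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Hub summary statistics
#'
#' Connections per gene = distinct linked elements per gene; connections per
#' enhancer = distinct linked genes per element; the elements-per-hub
#' histogram counts all members (genes + elements) with an open-ended final
#' bin at 10.
#'
#' @param crhs A `crh_set`.
#' @return List: `n_hubs`, `n_edges`, `mean_connections_per_gene`,
#'   `mean_connections_per_enhancer`, `elements_per_hub` (named histogram),
#'   `mean_elements_per_hub`, `frac_hubs_lt5`, `frac_hubs_ge10`.
#' @export
hub_stats <- function(crhs) {
  edges <- unique(crhs$edges[c("element_id", "gene_id")])
  per_gene <- table(edges$gene_id)
  per_enh <- table(edges$element_id)
  sizes <- hub_sizes(crhs)
  breaks <- c(2:10, Inf)
  labels <- c(as.character(2:9), ">=10")
  hist <- table(cut(sizes, breaks = breaks, labels = labels, right = FALSE))
  list(n_hubs = length(sizes),
       n_edges = nrow(edges),
       mean_connections_per_gene = mean(as.numeric(per_gene)),
       mean_connections_per_enhancer = mean(as.numeric(per_enh)),
       elements_per_hub = stats::setNames(as.integer(hist), labels),
       mean_elements_per_hub = mean(as.numeric(sizes)),
       frac_hubs_lt5 = mean(sizes < 5),
       frac_hubs_ge10 = mean(sizes >= 10))
}

#' Shared and condition-unique enhancer-gene pairs
#'
#' In `"locus"` mode a pair from one condition matches a pair from the other
#' when the element loci overlap by at least 1 bp and the gene ids are
#' equal; `"id"` mode requires equal element ids too.
#'
#' @param pairs_a,pairs_b Thresholded pair tables.
#' @param match `"locus"` (default) or `"id"`.
#' @return List of counts: `n_a`, `n_b`, `shared_a`, `shared_b`, `unique_a`,
#'   `unique_b`, `frac_shared_a`, `frac_shared_b`.
#' @export
shared_pairs <- function(pairs_a, pairs_b, match = c("locus", "id")) {
  match <- match.arg(match)
  if (nrow(pairs_a) && nrow(pairs_b) &&
      !length(intersect(unique(pairs_a$chrom), unique(pairs_b$chrom)))) {
    stop("no chromosome names shared between the two pair sets", call. = FALSE)
  }
  if (match == "id") {
    key_a <- paste(pairs_a$element_id, pairs_a$gene_id)
    key_b <- paste(pairs_b$element_id, pairs_b$gene_id)
    in_b <- key_a %in% key_b
    in_a <- key_b %in% key_a
  } else {
    hits <- overlap_pairs(pairs_a, pairs_b)
    hits <- hits[pairs_a$gene_id[hits$query] == pairs_b$gene_id[hits$subject], ,
                 drop = FALSE]
    in_b <- seq_len(nrow(pairs_a)) %in% hits$query
    in_a <- seq_len(nrow(pairs_b)) %in% hits$subject
  }
  list(n_a = nrow(pairs_a), n_b = nrow(pairs_b),
       shared_a = sum(in_b), shared_b = sum(in_a),
       unique_a = sum(!in_b), unique_b = sum(!in_a),
       frac_shared_a = if (nrow(pairs_a)) mean(in_b) else NA_real_,
       frac_shared_b = if (nrow(pairs_b)) mean(in_a) else NA_real_)
}

# match members across conditions: genes by id, elements by locus overlap.
# Returns data.frame (hub_a, hub_b, n_shared) plus per-hub member counts.
hub_mapping <- function(crhs_a, crhs_b) {
  mem_a <- crhs_a$membership
  mem_b <- crhs_b$membership
  links <- list()
  ga <- mem_a[mem_a$member_type == "gene", ]
  gb <- mem_b[mem_b$member_type == "gene", ]
  m <- match(ga$member_id, gb$member_id)
  ok <- !is.na(m)
  if (any(ok)) {
    links[[1]] <- data.frame(hub_a = ga$hub_id[ok], hub_b = gb$hub_id[m[ok]],
                             stringsAsFactors = FALSE)
  }
  ea <- mem_a[mem_a$member_type == "element", ]
  eb <- mem_b[mem_b$member_type == "element", ]
  hits <- overlap_pairs(ea, eb)
  if (nrow(hits)) {
    links[[2]] <- data.frame(hub_a = ea$hub_id[hits$query],
                             hub_b = eb$hub_id[hits$subject],
                             stringsAsFactors = FALSE)
  }
  if (length(links)) {
    map <- do.call(rbind, links)
    agg <- stats::aggregate(list(n_shared = rep(1L, nrow(map))),
                            by = map[c("hub_a", "hub_b")], FUN = sum)
  } else {
    agg <- data.frame(hub_a = character(), hub_b = character(),
                      n_shared = integer(), stringsAsFactors = FALSE)
  }
  agg
}

# Jaccard over matched member loci between one hub in A and one in B:
# shared = gene ids in common + element locus matches (counted once per
# member on each side, averaged), union = |A| + |B| - shared.
hub_jaccard <- function(crhs_a, crhs_b, hub_a, hub_b) {
  mem_a <- crhs_a$membership[crhs_a$membership$hub_id == hub_a, ]
  mem_b <- crhs_b$membership[crhs_b$membership$hub_id == hub_b, ]
  shared_genes <- length(intersect(
    mem_a$member_id[mem_a$member_type == "gene"],
    mem_b$member_id[mem_b$member_type == "gene"]))
  ea <- mem_a[mem_a$member_type == "element", ]
  eb <- mem_b[mem_b$member_type == "element", ]
  hits <- overlap_pairs(ea, eb)
  # count each matched member once per side, then average the two sides so
  # one-to-many locus matches cannot push the intersection past either set
  shared_el <- (length(unique(hits$query)) + length(unique(hits$subject))) / 2
  shared <- shared_genes + shared_el
  union <- nrow(mem_a) + nrow(mem_b) - shared
  if (union <= 0) return(1)
  shared / union
}

#' Compare hubs between two conditions
#'
#' Hubs are matched across conditions by shared members (genes by id,
#' elements by locus overlap). Each condition-A hub is labeled:
#' \describe{
#'   \item{dissolved}{no condition-B hub shares a member}
#'   \item{split}{members map into two or more B hubs}
#'   \item{merged}{maps into one B hub that also holds members of other A
#'     hubs, or into a single B hub with member Jaccard below `jmin`}
#'   \item{conserved}{one-to-one mapping with member Jaccard >= `jmin`}
#' }
#'
#' @param crhs_a,crhs_b `crh_set` objects (A is the reference/control).
#' @param jmin Minimum Jaccard for `conserved` (default 0.5).
#' @param simple_max_size Hubs with at most this many members count as
#'   "simple" in the merge summary (default 3, i.e. 2-3 members).
#' @return List with `labels` (per-hub data frame: `hub_id`, `label`,
#'   `n_b_hubs`, `best_b_hub`, `jaccard`), `mapping` (hub_a, hub_b,
#'   n_shared), `label_counts`, and `simple_merge` (simple-hub merge
#'   summary).
#' @export
compare_hubs <- function(crhs_a, crhs_b, jmin = 0.5, simple_max_size = 3) {
  hubs_a <- unique(crhs_a$membership$hub_id)
  map <- hub_mapping(crhs_a, crhs_b)
  # hubs in A per B hub (to detect merging)
  a_per_b <- tapply(map$hub_a, map$hub_b, function(x) length(unique(x)))
  labels <- vapply(hubs_a, function(h) {
    rows <- map[map$hub_a == h, , drop = FALSE]
    if (nrow(rows) == 0) return("dissolved")
    if (length(unique(rows$hub_b)) >= 2) return("split")
    b <- rows$hub_b[1]
    if (a_per_b[[b]] >= 2) return("merged")
    j <- hub_jaccard(crhs_a, crhs_b, h, b)
    if (j >= jmin) "conserved" else "merged"
  }, character(1))
  best_b <- vapply(hubs_a, function(h) {
    rows <- map[map$hub_a == h, , drop = FALSE]
    if (nrow(rows) == 0) return(NA_character_)
    rows$hub_b[order(-rows$n_shared, rows$hub_b)][1]
  }, character(1))
  jac <- vapply(seq_along(hubs_a), function(k) {
    if (is.na(best_b[k])) return(0)
    hub_jaccard(crhs_a, crhs_b, hubs_a[k], best_b[k])
  }, numeric(1))
  lab_df <- data.frame(hub_id = hubs_a, label = unname(labels),
                       n_b_hubs = vapply(hubs_a, function(h)
                         length(unique(map$hub_b[map$hub_a == h])), integer(1)),
                       best_b_hub = unname(best_b), jaccard = jac,
                       stringsAsFactors = FALSE)
  rownames(lab_df) <- NULL
  sizes <- hub_sizes(crhs_a)
  simple <- names(sizes)[sizes <= simple_max_size]
  simple_merged <- sum(lab_df$label == "merged" & lab_df$hub_id %in% simple)
  counts <- table(factor(lab_df$label,
                         levels = c("conserved", "merged", "split",
                                    "dissolved")))
  list(labels = lab_df, mapping = map,
       label_counts = stats::setNames(as.integer(counts), names(counts)),
       simple_merge = list(n_simple = length(simple),
                           n_simple_merged = simple_merged,
                           frac_simple_merged =
                             if (length(simple)) simple_merged / length(simple)
                             else NA_real_))
}

#' Site enrichment of hub elements between two conditions
#'
#' Builds the 2x2 table (rows: condition A vs B hub member elements;
#' columns: element overlaps at least one site vs not), and reports the odds
#' ratio with a two-sided exact p-value computed by direct hypergeometric
#' tail summation (all tables with fixed margins whose probability does not
#' exceed the observed table's).
#'
#' @param crhs_a,crhs_b `crh_set` objects.
#' @param sites Interval data frame (e.g. CTCF binding sites).
#' @return List: `table` (2x2 matrix), `odds_ratio`, `p_value`,
#'   `haldane_corrected` flag (0.5 added to all cells when a zero cell makes
#'   the OR undefined).
#' @export
site_enrichment <- function(crhs_a, crhs_b, sites) {
  count_side <- function(crhs) {
    el <- crhs$membership[crhs$membership$member_type == "element", ]
    if (nrow(el) == 0) return(c(0L, 0L))
    hit <- seq_len(nrow(el)) %in% overlap_pairs(el, sites)$query
    c(sum(hit), sum(!hit))
  }
  ab <- count_side(crhs_a)
  cd <- count_side(crhs_b)
  tab <- matrix(c(ab, cd), nrow = 2, byrow = TRUE,
                dimnames = list(condition = c("A", "B"),
                                site = c("overlap", "no_overlap")))
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  haldane <- (b * cc == 0) || (a * d == 0)
  or <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  list(table = tab, odds_ratio = or,
       p_value = fisher_exact_p(a, b, cc, d),
       haldane_corrected = haldane)
}

#' Two-sided exact p for a 2x2 table by hypergeometric summation
#'
#' Sums, over all tables with the observed margins, the probabilities that do
#' not exceed the observed table's probability (with a small relative
#' tolerance against floating-point ties), the same convention as the
#' classical two-sided Fisher test.
#'
#' @param a,b,c,d Cell counts, rows (a, b) and (c, d).
#' @return The p-value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  if (k == 0 || k == m + n || m == 0 || n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Score distribution comparison between two conditions
#'
#' @param pairs_a,pairs_b Thresholded pair tables (each with at least 2
#'   pairs).
#' @return List with per-condition `n`, `max`, `mean`, `median` of
#'   `abc_score`, plus Welch two-sample `t_statistic` and `p_value`.
#' @export
score_distribution_report <- function(pairs_a, pairs_b) {
  if (nrow(pairs_a) < 2 || nrow(pairs_b) < 2) {
    stop("need at least 2 pairs per condition", call. = FALSE)
  }
  sa <- pairs_a$abc_score
  sb <- pairs_b$abc_score
  tt <- tryCatch(stats::t.test(sa, sb),
                 error = function(e) list(statistic = c(t = 0), p.value = 1))
  list(a = list(n = length(sa), max = max(sa), mean = mean(sa),
                median = stats::median(sa)),
       b = list(n = length(sb), max = max(sb), mean = mean(sb),
                median = stats::median(sb)),
       t_statistic = unname(tt$statistic), p_value = tt$p.value)
}
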