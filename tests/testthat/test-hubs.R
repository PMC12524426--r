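# helper: build a pair table from an edge list with synthetic loci
pairs_from_edges <- function(el_ids, gene_ids, chrom = "chr1") {
  els <- sort(unique(el_ids))
  gns <- sort(unique(gene_ids))
  el_start <- stats::setNames(seq_along(els) * 10000, els)
  g_tss <- stats::setNames(100000 + seq_along(gns) * 10000, gns)
  data.frame(element_id = el_ids, chrom = chrom,
             start = el_start[el_ids], end = el_start[el_ids] + 500,
             gene_id = gene_ids, tss = g_tss[gene_ids],
             distance = abs(el_start[el_ids] - g_tss[gene_ids]),
             activity = 1, contact = 1, abc_score = 0.5,
             stringsAsFactors = FALSE)
}

test_that("hubs are the connected components of the bipartite graph", {
  p <- pairs_from_edges(c("e1"), c("g1"))
  crhs <- build_crhs(p)
  expect_equal(length(unique(crhs$membership$hub_id)), 1)
  expect_equal(nrow(crhs$membership), 2)

  p2 <- pairs_from_edges(c("e1", "e1", "e2", "e3"),
                         c("g1", "g2", "g2", "g3"))
  crhs2 <- build_crhs(p2)
  sizes <- sort(as.integer(table(crhs2$membership$hub_id)))
  expect_equal(sizes, c(2, 4))
  big <- names(which.max(table(crhs2$membership$hub_id)))
  expect_setequal(
    crhs2$membership$member_id[crhs2$membership$hub_id == big],
    c("e1", "e2", "g1", "g2"))

  expect_equal(nrow(build_crhs(p2[0, ])$membership), 0)
  expect_warning(build_crhs(rbind(p, p)), "duplicate")
  bad <- pairs_from_edges("x1", "g1")
  bad$gene_id <- "x1"
  bad$element_id <- "x1"
  expect_error(suppressWarnings(build_crhs(bad)), "collide")
})

test_that("component labels agree with a BFS oracle on random graphs", {
  set.seed(19)
  for (rep in 1:10) {
    n_el <- sample(20:100, 1)
    n_gn <- sample(20:100, 1)
    n_edges <- sample(30:200, 1)
    edges <- unique(data.frame(
      from = paste0("e", sample(n_el, n_edges, replace = TRUE)),
      to = paste0("g", sample(n_gn, n_edges, replace = TRUE)),
      stringsAsFactors = FALSE))
    p <- pairs_from_edges(edges$from, edges$to)
    crhs <- build_crhs(p)
    oracle <- oracle_components(edges)
    got <- stats::setNames(crhs$membership$hub_id,
                           crhs$membership$member_id)
    # same partition: members share a hub iff they share an oracle component
    nodes <- names(oracle)
    expect_equal(length(unique(got)), length(unique(oracle)))
    split_oracle <- split(nodes, oracle[nodes])
    for (grp in split_oracle) {
      expect_equal(length(unique(got[grp])), 1)
    }
  }
})

test_that("hub statistics satisfy degree definitions and handshake identity", {
  p <- pairs_from_edges(c("e1", "e2"), c("g1", "g1"))
  st <- hub_stats(build_crhs(p))
  expect_equal(st$mean_connections_per_gene, 2)
  expect_equal(st$mean_connections_per_enhancer, 1)
  expect_equal(unname(st$elements_per_hub["3"]), 1L)

  # star hub: one gene, k elements
  k <- 7
  star <- pairs_from_edges(paste0("e", 1:k), rep("g1", k))
  st_star <- hub_stats(build_crhs(star))
  expect_equal(st_star$mean_connections_per_gene, k)

  # handshake: sum of degrees on both sides equals the edge count
  set.seed(5)
  edges <- unique(data.frame(
    from = paste0("e", sample(30, 80, replace = TRUE)),
    to = paste0("g", sample(30, 80, replace = TRUE))))
  crhs <- build_crhs(pairs_from_edges(edges$from, edges$to))
  st_r <- hub_stats(crhs)
  n_genes <- length(unique(edges$to))
  n_els <- length(unique(edges$from))
  expect_equal(st_r$mean_connections_per_gene * n_genes, nrow(edges))
  expect_equal(st_r$mean_connections_per_enhancer * n_els, nrow(edges))
})

test_that("shared pair counting distinguishes locus and id matching", {
  a <- pairs_from_edges(c("e1", "e2"), c("g1", "g2"))
  expect_equal(shared_pairs(a, a)$frac_shared_a, 1)
  b <- a
  b$start <- b$start + 100000
  b$end <- b$end + 100000
  expect_equal(shared_pairs(a, b, match = "locus")$shared_a, 0)
  # 1 bp overlapping loci, same gene: shared in locus mode, not in id mode
  c_ <- a
  c_$element_id <- paste0("other_", c_$element_id)
  c_$start <- c_$start + 499
  c_$end <- c_$end + 499
  expect_equal(shared_pairs(a, c_, match = "locus")$shared_a, 2)
  expect_equal(shared_pairs(a, c_, match = "id")$shared_a, 0)
})

test_that("hub comparison labels conserved, merged, split and dissolved", {
  a <- build_crhs(pairs_from_edges(c("e1", "e2", "e3"),
                                   c("g1", "g1", "g2")))
  expect_true(all(compare_hubs(a, a)$labels$label == "conserved"))

  # two disjoint control hubs absorbed into one KO hub -> both merged
  ctl <- build_crhs(pairs_from_edges(c("e1", "e2"), c("g1", "g2")))
  ko <- build_crhs(pairs_from_edges(c("e1", "e1", "e2"),
                                    c("g1", "g2", "g2")))
  cmp <- compare_hubs(ctl, ko)
  expect_equal(unname(cmp$labels$label), c("merged", "merged"))
  expect_equal(unname(cmp$label_counts["merged"]), 2L)
  expect_equal(cmp$simple_merge$n_simple, 2)
  expect_equal(cmp$simple_merge$frac_simple_merged, 1)

  # control hub with no overlapping KO member -> dissolved
  lost <- build_crhs(pairs_from_edges("e9", "g9"))
  lost$membership$start <- lost$membership$start + 5e6
  lost$membership$end <- lost$membership$end + 5e6
  cmp2 <- compare_hubs(lost, ko)
  expect_equal(cmp2$labels$label, "dissolved")

  # control hub whose members scatter over two KO hubs -> split
  ctl3 <- build_crhs(pairs_from_edges(c("e1", "e2"), c("g1", "g1")))
  ko3 <- build_crhs(pairs_from_edges(c("e1", "e2"), c("g1", "g7")))
  ko3$membership <- ko3$membership  # e2 now sits with g7 in another hub
  cmp3 <- compare_hubs(ctl3, ko3)
  expect_equal(cmp3$labels$label[1], "split")
})

test_that("hub comparison is stable under input order permutation", {
  set.seed(8)
  edges_a <- unique(data.frame(
    from = paste0("e", sample(15, 30, replace = TRUE)),
    to = paste0("g", sample(15, 30, replace = TRUE))))
  edges_b <- unique(data.frame(
    from = paste0("e", sample(15, 30, replace = TRUE)),
    to = paste0("g", sample(15, 30, replace = TRUE))))
  pa <- pairs_from_edges(edges_a$from, edges_a$to)
  pb <- pairs_from_edges(edges_b$from, edges_b$to)
  base <- compare_hubs(build_crhs(pa), build_crhs(pb))
  perm <- sample(nrow(pa))
  shuf <- compare_hubs(build_crhs(pa[perm, ]), build_crhs(pb))
  expect_equal(base$labels[order(base$labels$hub_id), ],
               shuf$labels[order(shuf$labels$hub_id), ])
})

test_that("site enrichment builds the 2x2 table and handles zero margins", {
  # equal proportions: OR 1, p 1
  a <- build_crhs(pairs_from_edges(paste0("e", 1:10), rep("g1", 10)))
  b <- build_crhs(pairs_from_edges(paste0("f", 1:10), rep("h1", 10)))
  b$membership$start <- b$membership$start + 1e6
  b$membership$end <- b$membership$end + 1e6
  # sites covering half of each side's elements (loci are deterministic)
  mem_a <- a$membership[a$membership$member_type == "element", ]
  mem_b <- b$membership[b$membership$member_type == "element", ]
  sites <- rbind(mem_a[1:5, c("chrom", "start", "end")],
                 mem_b[1:5, c("chrom", "start", "end")])
  enr <- site_enrichment(a, b, unique(sites))
  expect_equal(enr$odds_ratio, 1)
  expect_equal(enr$p_value, 1)

  # all of A overlaps, none of B: Haldane correction flagged
  enr2 <- site_enrichment(a, b, mem_a[, c("chrom", "start", "end")])
  expect_true(enr2$haldane_corrected)
  expect_gt(enr2$odds_ratio, 1)
})

test_that("exact test p-values match hypergeometric enumeration", {
  expect_equal(fisher_exact_p(10, 5, 5, 10), oracle_fisher_p(10, 5, 5, 10))
  # (10,5;5,10) has OR 4
  expect_equal((10 * 10) / (5 * 5), 4)
  expect_equal(fisher_exact_p(5, 5, 5, 5), 1)
  # agreement with stats::fisher.test on a sample of tables
  set.seed(2)
  for (rep in 1:25) {
    tb <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tb) == 0) next
    p <- fisher_exact_p(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    expect_equal(p, fisher.test(tb)$p.value, tolerance = 1e-9)
  }
})

test_that("score distribution report reduces to the closed-form t", {
  a <- data.frame(abc_score = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(score_distribution_report(a, a)$t_statistic, 0)
  set.seed(4)
  x <- rnorm(5000, 0.054, 0.02)
  y <- rnorm(5000, 0.028, 0.02)
  rep_ <- score_distribution_report(data.frame(abc_score = x),
                                    data.frame(abc_score = y))
  t_closed <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(rep_$t_statistic, t_closed, tolerance = 1e-6)
  expect_equal(rep_$a$mean, mean(x))
  expect_equal(rep_$b$max, max(y))
  expect_error(score_distribution_report(a[1, , drop = FALSE], a),
               "at least 2")
})
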