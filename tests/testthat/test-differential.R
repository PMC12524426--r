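test_that("log2 fold change helper follows the pseudocount arithmetic", {
  a <- c(x = 7, y = 0, z = 3)
  b <- c(x = 7, y = 7, z = 1)
  fc <- compute_log2fc(a, b)
  expect_equal(fc$log2fc[fc$feature_id == "x"], 0)
  expect_equal(fc$log2fc[fc$feature_id == "y"], 3)  # log2(8/1)
  # swapping conditions flips the sign exactly
  rev_fc <- compute_log2fc(b, a)
  expect_equal(rev_fc$log2fc, -fc$log2fc)
  expect_error(compute_log2fc(c(x = -1), c(x = 2)), "negative")
})

mk_pairs_lfc <- function(n, rho, seed = 1, scale = 1) {
  set.seed(seed)
  f <- rnorm(n)
  g <- scale * (sqrt(rho) * f + sqrt(1 - rho) * rnorm(n))
  e <- scale * (sqrt(rho) * f + sqrt(1 - rho) * rnorm(n))
  starts <- seq_len(n) * 1000
  pairs <- data.frame(element_id = paste0("e", seq_len(n)), chrom = "chr1",
                      start = starts, end = starts + 500,
                      gene_id = paste0("g", seq_len(n)),
                      tss = starts + 100, distance = 100, activity = 1,
                      contact = 1, abc_score = 0.5, stringsAsFactors = FALSE)
  gene_lfc <- data.frame(feature_id = pairs$gene_id, log2fc = g)
  enh_lfc <- data.frame(feature_id = paste0("pk", seq_len(n)),
                        chrom = "chr1", start = starts, end = starts + 500,
                        log2fc = e)
  list(pairs = pairs, gene = gene_lfc, enh = enh_lfc)
}

test_that("pair correlation recovers identity and planted rho", {
  d <- mk_pairs_lfc(50, 0)
  d$enh$log2fc <- d$gene$log2fc  # enhancer change == gene change
  r1 <- eg_change_correlation(d$pairs, d$gene, d$enh)
  expect_equal(r1$r, 1)

  d2 <- mk_pairs_lfc(10000, 0.5, seed = 7)
  r2 <- eg_change_correlation(d2$pairs, d2$gene, d2$enh)
  expect_gt(r2$r, 0.47)
  expect_lt(r2$r, 0.53)
  expect_lt(r2$p, 1e-10)

  # raising the |lfc| filter never increases n
  ns <- vapply(c(0, 0.2, 0.5, 1),
               function(th) eg_change_correlation(d2$pairs, d2$gene, d2$enh,
                                                  min_abs_lfc = th)$n,
               numeric(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(eg_change_correlation(d$pairs[1:2, ], d$gene, d$enh),
               "at least 3")
})

test_that("pearson matches the closed form and is affine invariant", {
  x <- c(1.2, -0.5, 3.1, 0.4, 2.2, -1.7)
  y <- c(0.3, -1.2, 2.5, 0.8, 1.1, -0.9)
  r_closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- crhub:::pearson_with_p(x, y)
  expect_equal(got$r, r_closed, tolerance = 1e-12)
  shifted <- crhub:::pearson_with_p(3 * x + 2, -0.5 * y + 1)
  expect_equal(abs(shifted$r), abs(r_closed), tolerance = 1e-12)
})

test_that("hub co-regulation includes indirect co-resident combinations", {
  # hub {g1, e1, e2} with edges only (e1, g1): combination (e2, g1) counted
  pairs <- data.frame(element_id = c("e1", "e2"), chrom = "chr1",
                      start = c(1000, 2000), end = c(1500, 2500),
                      gene_id = c("g1", "g1"), tss = 5000, distance = 1,
                      activity = 1, contact = 1, abc_score = 0.5,
                      stringsAsFactors = FALSE)
  crhs <- build_crhs(pairs)
  gene_lfc <- data.frame(feature_id = c("g1", "g2", "g3"),
                         log2fc = c(1, -1, 0.5))
  enh_lfc <- data.frame(feature_id = c("p1", "p2"), chrom = "chr1",
                        start = c(1000, 2000), end = c(1500, 2500),
                        log2fc = c(0.8, 1.2))
  # only 2 observations here, so extend with a second hub for n >= 3
  pairs2 <- rbind(pairs, data.frame(element_id = "e3", chrom = "chr1",
                                    start = 1e6, end = 1e6 + 500,
                                    gene_id = "g2", tss = 2e6, distance = 1,
                                    activity = 1, contact = 1,
                                    abc_score = 0.5))
  enh_lfc2 <- rbind(enh_lfc, data.frame(feature_id = "p3", chrom = "chr1",
                                        start = 1e6, end = 1e6 + 500,
                                        log2fc = -0.7))
  res <- hub_coregulation(build_crhs(pairs2), gene_lfc, enh_lfc2)
  expect_equal(res$n, 3)  # (g1,e1), (g1,e2), (g2,e3)
  # enumeration oracle
  obs <- data.frame(g = c(1, 1, -1), e = c(0.8, 1.2, -0.7))
  expect_equal(res$r, cor(obs$g, obs$e), tolerance = 1e-12)
  # direct-only mode drops nothing here (all combos are edges in pairs2)
  res_direct <- hub_coregulation(build_crhs(pairs2), gene_lfc, enh_lfc2,
                                 direct_only = TRUE)
  expect_equal(res_direct$n, 3)
})

test_that("single-edge hubs reduce hub co-regulation to pair correlation", {
  d <- mk_pairs_lfc(200, 0.3, seed = 3)
  r_pair <- eg_change_correlation(d$pairs, d$gene, d$enh)
  r_hub <- hub_coregulation(build_crhs(d$pairs), d$gene, d$enh)
  expect_equal(r_hub$r, r_pair$r, tolerance = 1e-12)
  expect_equal(r_hub$n, r_pair$n)
})

test_that("gene ranking is deterministic with lexicographic tie-break", {
  genes <- toy_genes(c(1e4, 2e4, 3e4, 4e4),
                     expression = c(5, 5, 9, 1),
                     ids = c("gB", "gA", "gC", "gD"))
  expect_equal(rank_genes_by_expression(genes, 3), c("gC", "gA", "gB"))
  # all equal: lexicographic prefix
  genes$expression <- 2
  expect_equal(rank_genes_by_expression(genes, 2), c("gA", "gB"))
  expect_error(rank_genes_by_expression(genes, 10), "exceeds")
})

test_that("hub sizes split by gene set give a calibrated rank-sum z", {
  # planted design: top genes in size-10 hubs, others in size-2 hubs
  big <- do.call(rbind, lapply(1:6, function(k) {
    data.frame(element_id = paste0("bige", k, "_", 1:9), chrom = "chr1",
               start = k * 1e5 + (1:9) * 1000,
               end = k * 1e5 + (1:9) * 1000 + 500,
               gene_id = paste0("topg", k), tss = k * 1e5, distance = 1,
               activity = 1, contact = 1, abc_score = 0.5)
  }))
  small <- do.call(rbind, lapply(1:8, function(k) {
    data.frame(element_id = paste0("sm", k), chrom = "chr1",
               start = 5e6 + k * 1e5, end = 5e6 + k * 1e5 + 500,
               gene_id = paste0("lowg", k), tss = 5e6 + k * 1e5 + 2000,
               distance = 1, activity = 1, contact = 1, abc_score = 0.5)
  }))
  crhs <- build_crhs(rbind(big, small))
  res <- hub_size_by_gene_set(crhs, paste0("topg", 1:6))
  expect_true(all(res$sizes_in == 10))
  expect_true(all(res$sizes_out == 2))
  expect_lt(res$p, 0.01)
  expect_gt(res$z, 0)
  # matches wilcox.test normal approximation without continuity correction
  w <- wilcox.test(res$sizes_in, res$sizes_out, exact = FALSE,
                   correct = FALSE)
  expect_equal(res$p, w$p.value, tolerance = 1e-10)
  # identical distributions: standardized statistic about zero
  same <- hub_size_by_gene_set(crhs, c(paste0("topg", 1:3),
                                       paste0("lowg", 1:4)))
  expect_lt(abs(same$z), 2)
})
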