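test_that("candidate definition merges peaks, pads widths and flags promoters", {
  atac <- toy_peaks(100, 600, 5)
  k27 <- toy_peaks(400, 900, 3)
  cand <- define_candidates(atac, k27, NULL, min_width = 100,
                            max_width = 10000)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 100)
  expect_equal(cand$end, 900)

  # ATAC-only peak is retained (and/or rule)
  cand2 <- define_candidates(toy_peaks(c(100, 5000), c(600, 5500), c(5, 2)),
                             k27, NULL, min_width = 100, max_width = 10000)
  expect_equal(nrow(cand2), 2)

  # promoter-proximal flagging against a brute-force overlap scan
  proms <- data.frame(chrom = "chr1", start = 450, end = 1450)
  cand3 <- define_candidates(atac, k27, proms, min_width = 100,
                             max_width = 10000)
  expect_true(cand3$promoter_proximal[1])
  far <- define_candidates(atac, k27,
                           data.frame(chrom = "chr1", start = 5000,
                                      end = 6000),
                           min_width = 100, max_width = 10000)
  expect_false(far$promoter_proximal[1])

  # width clipping and padding around the midpoint
  wide <- define_candidates(toy_peaks(0, 40000, 1), toy_peaks(0, 40000, 1),
                            NULL, min_width = 500, max_width = 10000)
  expect_equal(wide$end - wide$start, 10000)
  narrow <- define_candidates(toy_peaks(1000, 1100, 1),
                              toy_peaks(1000, 1100, 1), NULL,
                              min_width = 500, max_width = 10000)
  expect_equal(narrow$end - narrow$start, 500)

  expect_error(define_candidates(toy_peaks(numeric(), numeric(), numeric()),
                                 toy_peaks(numeric(), numeric(), numeric()),
                                 NULL),
               "no candidate")
})

test_that("activity is the geometric mean of overlap-weighted signals", {
  el <- data.frame(element_id = "e1", chrom = "chr1", start = 0, end = 1000,
                   promoter_proximal = FALSE)
  atac <- toy_peaks(0, 1000, 4)
  k27 <- toy_peaks(0, 1000, 9)
  a <- compute_activity(el, atac, k27, pseudocount = 0)
  expect_equal(a$activity, 6)

  # both assays zero: pseudocount floor
  none <- toy_peaks(5000, 6000, 1)
  a0 <- compute_activity(el, none, none, pseudocount = 0.1)
  expect_equal(a0$activity, 0.1)

  # half-overlapping peak contributes signal * 0.5 (per-base integration)
  half <- toy_peaks(500, 1500, 8)
  ah <- compute_activity(el, half, k27, pseudocount = 0)
  expect_equal(ah$atac_signal, 4)
  # per-base oracle: uniform density 8/1000 over 500 covered bases
  expect_equal(ah$atac_signal, sum(rep(8 / 1000, 500)))

  expect_error(compute_activity(el, toy_peaks(0, 10, -1), k27), "negative")
})

test_that("contact extraction uses bin lookup plus decay pseudocount", {
  n <- 60
  m <- outer(seq_len(n), seq_len(n),
             function(i, j) 100 / pmax(abs(i - j), 1))
  cm <- contact_matrix_from_dense(m, resolution = 10000)
  decay <- fit_contact_decay(cm)
  # adjacent bins: direct lookup dominates
  c1 <- extract_contact(cm, 5000, 15000, decay, pseudocount_frac = 1e-9)
  expect_equal(c1, 100, tolerance = 1e-6)
  # zero stored count: strictly positive pseudocount
  m2 <- m
  m2[1, 11] <- m2[11, 1] <- 0
  cm2 <- contact_matrix_from_dense(m2, resolution = 10000)
  c0 <- extract_contact(cm2, 5000, 105000, decay)
  expect_gt(c0, 0)
  expect_lt(c0, 1)
  expect_error(extract_contact(cm, 5000, 1e9, decay), "outside")
})

test_that("decay fit recovers a known power law within 10%", {
  n <- 200
  k_true <- 500
  a_true <- 1.2
  m <- outer(seq_len(n), seq_len(n), function(i, j) {
    d <- pmax(abs(i - j), 1) * 10000
    k_true * (d / 10000)^(-a_true)
  })
  cm <- contact_matrix_from_dense(m, resolution = 10000)
  fit <- fit_contact_decay(cm)
  expect_equal(fit$alpha, a_true, tolerance = 0.1)
  # independent log-log regression oracle on the binned means
  prof <- fit$profile
  o <- lm(log(mean_count) ~ log(offset_bins * 10000),
          data = prof[prof$mean_count > 0, ])
  expect_equal(fit$alpha, -unname(coef(o)[2]), tolerance = 1e-8)
})

test_that("ABC normalization matches hand evaluation and sums to one", {
  n <- 100
  m <- outer(seq_len(n), seq_len(n),
             function(i, j) 50 / pmax(abs(i - j), 1))
  cm <- contact_matrix_from_dense(m, resolution = 10000)
  # single element in the window: score 1 regardless of magnitudes
  el1 <- data.frame(element_id = "e1", chrom = "chr1", start = 100000,
                    end = 101000, promoter_proximal = FALSE, activity = 7)
  genes <- toy_genes(500000)
  p1 <- compute_abc_scores(el1, genes, cm, pseudocount_frac = 1e-12)
  expect_equal(p1$abc_score, 1)

  # two elements with A*C products 8 and 2 -> 0.8 / 0.2
  cm_flat <- contact_matrix_from_dense(matrix(1, 50, 50) +
                                         diag(50), resolution = 10000)
  el2 <- data.frame(element_id = c("e1", "e2"), chrom = "chr1",
                    start = c(100000, 200000), end = c(101000, 201000),
                    promoter_proximal = FALSE, activity = c(8, 2))
  p2 <- compute_abc_scores(el2, toy_genes(300000), cm_flat,
                           pseudocount_frac = 1e-12)
  expect_equal(sort(p2$abc_score), c(0.2, 0.8), tolerance = 1e-6)
})

test_that("ABC scores equal brute-force formula evaluation on toy windows", {
  set.seed(11)
  for (rep in 1:5) {
    n_el <- sample(3:20, 1)
    n <- 300
    m <- matrix(rpois(n * n, 5) + 1, n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    cm <- contact_matrix_from_dense(m, resolution = 10000)
    starts <- sort(sample(seq(10000, 2.8e6, by = 2000), n_el))
    el <- data.frame(element_id = sprintf("e%02d", seq_len(n_el)),
                     chrom = "chr1", start = starts, end = starts + 1000,
                     promoter_proximal = FALSE,
                     activity = runif(n_el, 0.5, 20))
    genes <- toy_genes(c(1.2e6, 2.1e6))
    decay <- fit_contact_decay(cm)
    pairs <- compute_abc_scores(el, genes, cm, decay = decay)
    # independent brute-force evaluation
    for (g in seq_len(nrow(genes))) {
      tss <- genes$tss[g]
      mid <- floor((el$start + el$end) / 2)
      inw <- abs(mid - tss) <= 2.5e6
      contact <- vapply(which(inw), function(k) {
        raw <- m[floor(mid[k] / 10000) + 1, floor(tss / 10000) + 1]
        raw + 0.01 * decay$k * max(abs(mid[k] - tss), 10000)^(-decay$alpha)
      }, numeric(1))
      w <- el$activity[inw] * contact
      expected <- w / sum(w)
      got <- pairs[pairs$gene_id == genes$gene_id[g], ]
      got <- got[match(el$element_id[inw], got$element_id), ]
      expect_equal(got$abc_score, unname(expected), tolerance = 1e-12)
    }
    sums <- tapply(pairs$abc_score, pairs$gene_id, sum)
    expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
  }
})

test_that("ABC is scale invariant and monotone in activity", {
  m <- matrix(3, 80, 80) + diag(80)
  cm <- contact_matrix_from_dense(m, resolution = 10000)
  starts <- seq(50000, 450000, by = 50000)
  el <- data.frame(element_id = sprintf("e%02d", seq_along(starts)),
                   chrom = "chr1", start = starts, end = starts + 1000,
                   promoter_proximal = FALSE,
                   activity = seq_along(starts))
  genes <- toy_genes(250000)
  base <- compute_abc_scores(el, genes, cm)
  # multiplying all activities by a constant changes nothing
  el_scaled <- el
  el_scaled$activity <- el$activity * 37.5
  expect_equal(compute_abc_scores(el_scaled, genes, cm)$abc_score,
               base$abc_score, tolerance = 1e-12)
  # scaling the whole matrix changes nothing
  cm_scaled <- contact_matrix_from_dense(m * 11, resolution = 10000)
  expect_equal(compute_abc_scores(el, genes, cm_scaled)$abc_score,
               base$abc_score, tolerance = 1e-9)
  # raising one element's activity raises its score, lowers the others
  el_up <- el
  el_up$activity[3] <- el$activity[3] * 2
  up <- compute_abc_scores(el_up, genes, cm)
  pick <- function(p, id) p$abc_score[p$element_id == id]
  expect_gt(pick(up, "e03"), pick(base, "e03"))
  for (id in setdiff(el$element_id, "e03")) {
    expect_lt(pick(up, id), pick(base, id))
  }
})

test_that("thresholding filters by cutoff and validates its domain", {
  pairs <- data.frame(element_id = c("a", "b", "c"),
                      gene_id = "g", abc_score = c(0.5, 0.011, 0.009))
  kept <- threshold_pairs(pairs, 0.01)
  expect_equal(nrow(kept), 2)
  expect_equal(attr(kept, "n_elements"), 2)
  expect_error(threshold_pairs(pairs, 0), "strictly inside")
  expect_error(threshold_pairs(pairs, 1), "strictly inside")
  # brute-force filter oracle on random vectors
  set.seed(3)
  rnd <- data.frame(element_id = paste0("e", 1:500), gene_id = "g",
                    abc_score = runif(500))
  for (cut in c(0.05, 0.3, 0.9)) {
    expect_equal(nrow(threshold_pairs(rnd, cut)),
                 sum(rnd$abc_score >= cut))
  }
})

test_that("distance statistics split top and bottom score bands", {
  # equidistant pairs: identical band summaries
  eq <- data.frame(element_id = paste0("e", 1:200), gene_id = "g",
                   abc_score = seq(0.9, 0.01, length.out = 200),
                   distance = 5e4)
  s <- pair_distance_stats(eq, 0.01)
  expect_equal(s$top$mean, s$bottom$mean)
  expect_equal(s$n_band, 2)

  # scores inversely proportional to distance: top band closer
  d <- seq(1e4, 2e6, length.out = 300)
  inv <- data.frame(element_id = paste0("e", seq_along(d)), gene_id = "g",
                    abc_score = 1e4 / d, distance = d)
  s2 <- pair_distance_stats(inv, 0.05)
  expect_lt(s2$top$median, s2$bottom$median)
  # sorting oracle
  ord <- order(-inv$abc_score)
  expect_equal(s2$top$mean, mean(d[ord[1:15]]))

  # band of one: mean = median
  s3 <- pair_distance_stats(inv[1:100, ], 0.01)
  expect_equal(s3$n_band, 1)
  expect_equal(s3$top$mean, s3$top$median)
  expect_error(pair_distance_stats(inv[1:5, ], 0.01), "at least")
})
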