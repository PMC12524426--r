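# Small in-code fixtures shared across test files.

toy_peaks <- function(starts, ends, signals, chrom = "chr1",
                      names = NULL) {
  df <- data.frame(chrom = rep(chrom, length.out = length(starts)),
                   start = starts, end = ends,
                   name = names %||% sprintf("p%d", seq_along(starts)),
                   signal = signals, stringsAsFactors = FALSE)
  crhub:::sort_intervals(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_genes <- function(tss, expression = NULL, chrom = "chr1",
                      ids = NULL) {
  data.frame(gene_id = ids %||% sprintf("g%02d", seq_along(tss)),
             chrom = chrom, tss = tss,
             strand = rep("+", length(tss)),
             expression = expression %||% rep(10, length(tss)),
             stringsAsFactors = FALSE)
}

# dense symmetric toy contact matrix with optional TAD block structure
toy_block_matrix <- function(n_bins, boundary = NULL, within = 10,
                             between = 1, resolution = 10000) {
  m <- matrix(between, n_bins, n_bins)
  if (is.null(boundary)) {
    m[] <- within
  } else {
    blocks <- list(seq_len(boundary), seq(boundary + 1, n_bins))
    for (b in blocks) m[b, b] <- within
  }
  contact_matrix_from_dense(m, resolution = resolution)
}

# brute-force directionality index on a dense matrix (independent oracle)
oracle_di <- function(mat, w) {
  n <- nrow(mat)
  di <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    A <- sum(mat[i, (i - w):(i - 1)])
    B <- sum(mat[i, (i + 1):(i + w)])
    E <- (A + B) / 2
    di[i] <- if (E == 0 || A == B) 0 else {
      sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
    }
  }
  di
}

# brute-force connected components of a bipartite edge list via BFS
oracle_components <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  adj <- split(c(edges$to, edges$from), c(edges$from, edges$to))
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    k <- k + 1L
    queue <- start
    comp[start] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (nb in adj[[v]]) {
        if (is.na(comp[nb])) {
          comp[nb] <- k
          queue <- c(queue, nb)
        }
      }
    }
  }
  comp
}

# two-sided Fisher p by full table enumeration with choose() (oracle)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  tot <- choose(m + n, k)
  probs <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(n, k - x) / tot
  }, numeric(1))
  p_obs <- choose(m, a) * choose(n, k - a) / tot
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
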