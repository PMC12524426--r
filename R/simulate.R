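# Synthetic paired-condition data with planted ground truth. One chromosome
# is partitioned into equal TADs; each TAD hosts one planted hub whose genes
# and enhancers live inside the TAD body (a margin around each boundary is
# kept element-free, mimicking the depleted regulatory density at real
# boundaries). Contacts follow a power-law distance decay, scaled down
# across TAD boundaries by the insulation factor, with planted loops between
# each gene and its dominant enhancer. The "KO" condition emulates CTCF loss:
# boundary insulation is attenuated (the between-TAD contact scale rises
# toward 1) and boundary-anchored loops are removed.

#' Simulation configuration
#'
#' Defaults describe a desk-scale chromosome: 20 Mb at 10 kb resolution
#' (2,000 bins), 60 genes and 300 enhancers in 10 TADs, one planted hub per
#' TAD.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param resolution Contact-matrix bin width in bp.
#' @param n_genes,n_enhancers,n_tads Element counts; genes and enhancers are
#'   split evenly over the planted hubs (one per TAD by default).
#' @param insulation Between-TAD contact scale in \[0, 1\] for the control
#'   condition (1 = no boundaries, 0 = absolute boundaries).
#' @param ko_insulation Between-TAD scale for the KO condition; must exceed
#'   `insulation` (CTCF loss weakens boundaries) and lie in (insulation, 1].
#' @param decay_exponent Power-law exponent alpha of the distance decay.
#' @param contact_scale Expected count at one-bin separation.
#' @param loop_strength Multiplier applied at planted loop bin pairs.
#' @param noise_dispersion Negative-binomial dispersion of realized counts
#'   (variance = mu + dispersion * mu^2); 0 means noise-free expected
#'   counts.
#' @param coregulation_rho Planted gene/enhancer fold-change correlation
#'   within a hub, in \[-1, 1\].
#' @param strong_fraction Fraction of hubs drawn with inflated effects.
#' @param strong_rho,strong_scale Correlation and fold-change scale of the
#'   strong-effect hubs.
#' @param boundary_margin Element-free margin on each side of every TAD
#'   boundary, bp.
#' @param ctcf_within_fraction Extra within-TAD CTCF sites as a fraction of
#'   `n_enhancers` (boundaries always get one site each).
#' @param enhancer_cluster_sd Enhancers are placed around the TSSs of their
#'   hub's genes with this Gaussian spread in bp (regulatory elements
#'   cluster near the genes they serve); positions are clipped to the hub
#'   span.
#' @param tss_exclusion Enhancers are kept at least this far from every TSS
#'   (bp): the generator plants distal elements, and anything closer sits in
#'   promoter territory, which the scoring treats separately.
#' @param peak_width Enhancer peak width in bp.
#' @param signal_meanlog,signal_sdlog Log-normal parameters of enhancer
#'   signal.
#' @param dominant_activity_mult Activity multiplier of each gene's planted
#'   dominant enhancer.
#' @param dominant_min_dist Minimum TSS distance of the dominant enhancer in
#'   bp: dominants are distal elements, and the planted loop anchors must be
#'   separated by many bins to be resolvable at the matrix resolution (and
#'   usable by APA flanks).
#' @param expression_meanlog,expression_sdlog Log-normal parameters of gene
#'   expression (FPKM-like).
#' @param max_dist_bins Contacts are materialized up to this bin offset
#'   (expected counts beyond it are negligible under the default decay).
#'
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              chrom = "chr1",
                              chrom_length = 20e6,
                              resolution = 1e4,
                              n_genes = 60L,
                              n_enhancers = 300L,
                              n_tads = 10L,
                              insulation = 0.1,
                              ko_insulation = 0.6,
                              decay_exponent = 1,
                              contact_scale = 1000,
                              loop_strength = 5,
                              noise_dispersion = 0.1,
                              coregulation_rho = 0.3,
                              strong_fraction = 0.2,
                              strong_rho = 0.7,
                              strong_scale = 2,
                              boundary_margin = 5e5,
                              ctcf_within_fraction = 0.1,
                              enhancer_cluster_sd = 1e5,
                              tss_exclusion = 2.5e4,
                              peak_width = 600,
                              signal_meanlog = 1,
                              signal_sdlog = 0.3,
                              dominant_activity_mult = 10,
                              dominant_min_dist = 2.5e5,
                              expression_meanlog = 2,
                              expression_sdlog = 1,
                              max_dist_bins = 300L) {
  cfg <- list(seed = as.integer(seed), chrom = chrom,
              chrom_length = chrom_length, resolution = resolution,
              n_genes = as.integer(n_genes),
              n_enhancers = as.integer(n_enhancers),
              n_tads = as.integer(n_tads),
              insulation = insulation, ko_insulation = ko_insulation,
              decay_exponent = decay_exponent, contact_scale = contact_scale,
              loop_strength = loop_strength,
              noise_dispersion = noise_dispersion,
              coregulation_rho = coregulation_rho,
              strong_fraction = strong_fraction, strong_rho = strong_rho,
              strong_scale = strong_scale,
              boundary_margin = boundary_margin,
              ctcf_within_fraction = ctcf_within_fraction,
              enhancer_cluster_sd = enhancer_cluster_sd,
              tss_exclusion = tss_exclusion,
              peak_width = peak_width, signal_meanlog = signal_meanlog,
              signal_sdlog = signal_sdlog,
              dominant_activity_mult = dominant_activity_mult,
              dominant_min_dist = dominant_min_dist,
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              max_dist_bins = as.integer(max_dist_bins))
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$chrom_length > 0, cfg$resolution > 0,
            cfg$chrom_length %% cfg$resolution == 0,
            cfg$n_genes >= 0, cfg$n_enhancers > 0, cfg$n_tads >= 1,
            cfg$peak_width > 0, cfg$contact_scale > 0,
            cfg$loop_strength >= 1, cfg$noise_dispersion >= 0)
  if (cfg$decay_exponent <= 0) {
    stop("decay_exponent must be positive", call. = FALSE)
  }
  if (cfg$insulation < 0 || cfg$insulation > 1) {
    stop("insulation must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$ko_insulation <= cfg$insulation || cfg$ko_insulation > 1) {
    stop(paste("ko_insulation must lie in (insulation, 1]:",
               "the KO condition emulates CTCF loss and must weaken",
               "boundary insulation"), call. = FALSE)
  }
  if (abs(cfg$coregulation_rho) > 1 || abs(cfg$strong_rho) > 1) {
    stop("correlation parameters must lie in [-1, 1]", call. = FALSE)
  }
  tad_bp <- cfg$chrom_length / cfg$n_tads
  if (2 * cfg$boundary_margin >= tad_bp) {
    stop("hub spans exceed chromosome: boundary margins leave no TAD body",
         call. = FALSE)
  }
  invisible(cfg)
}

# equal-sized TADs; internal boundary bins (0-based, start bin of each TAD
# after the first)
planted_boundaries <- function(cfg) {
  n_bins <- cfg$chrom_length / cfg$resolution
  if (cfg$n_tads < 2) return(integer(0))
  round(seq_len(cfg$n_tads - 1) * n_bins / cfg$n_tads)
}

tad_of_bin <- function(bins, boundary_bins) {
  findInterval(bins, boundary_bins) + 1L
}

#' Simulate the genomic landscape: genes, peaks, CTCF sites
#'
#' Genes and enhancers are placed uniformly within each planted hub span
#' (the TAD body minus the boundary margins). Each enhancer carries an ATAC
#' and an H3K27ac peak whose signals share a log-normal factor; each gene's
#' nearest free enhancer becomes its dominant enhancer (activity boosted by
#' `dominant_activity_mult`, and later linked by a planted loop).
#'
#' @param config A `sim_config`.
#' @return List: `genes`, `atac`, `h3k27ac` (peak tables), `ctcf_sites`,
#'   and `truth` (planted boundaries, hub memberships, dominant-enhancer
#'   map, enhancer loci).
#' @export
simulate_genome <- function(config) {
  cfg <- validate_config(config)
  set.seed(cfg$seed)
  n_bins <- cfg$chrom_length / cfg$resolution
  bounds <- planted_boundaries(cfg)
  tad_edges_bp <- c(0, bounds * cfg$resolution, cfg$chrom_length)
  n_hubs <- cfg$n_tads
  span_lo <- tad_edges_bp[-length(tad_edges_bp)] + cfg$boundary_margin
  span_hi <- tad_edges_bp[-1] - cfg$boundary_margin

  per_hub_genes <- diff(round(seq(0, cfg$n_genes, length.out = n_hubs + 1)))
  per_hub_enh <- diff(round(seq(0, cfg$n_enhancers,
                                length.out = n_hubs + 1)))

  genes <- data.frame(gene_id = character(), chrom = character(),
                      tss = numeric(), strand = character(),
                      expression = numeric(), hub = integer(),
                      stringsAsFactors = FALSE)
  enh <- data.frame(enh_id = character(), chrom = character(),
                    start = numeric(), end = numeric(), hub = integer(),
                    stringsAsFactors = FALSE)
  for (h in seq_len(n_hubs)) {
    ng <- per_hub_genes[h]; ne <- per_hub_enh[h]
    if (ng > 0) {
      tss <- sort(round(stats::runif(ng, span_lo[h], span_hi[h])))
      genes <- rbind(genes, data.frame(
        gene_id = "", chrom = cfg$chrom, tss = tss,
        strand = sample(c("+", "-"), ng, replace = TRUE),
        expression = round(stats::rlnorm(ng, cfg$expression_meanlog,
                                         cfg$expression_sdlog), 3),
        hub = h, stringsAsFactors = FALSE))
    }
    if (ne > 0) {
      lo_h <- span_lo[h] + cfg$peak_width
      hi_h <- span_hi[h] - cfg$peak_width
      if (ng > 0) {
        # enhancers cluster around the genes they serve, outside the
        # TSS-proximal exclusion zone (planted elements are distal)
        tss_h <- genes$tss[genes$hub == h]
        draw <- function(n) {
          anchor <- tss_h[sample.int(ng, n, replace = TRUE)]
          pos <- round(anchor + stats::rnorm(n, 0, cfg$enhancer_cluster_sd))
          pmin(pmax(pos, lo_h), hi_h)
        }
        ctr <- draw(ne)
        for (try in 1:50) {
          too_close <- vapply(ctr, function(p)
            any(abs(p - tss_h) < cfg$tss_exclusion), logical(1))
          if (!any(too_close)) break
          ctr[too_close] <- draw(sum(too_close))
        }
        ctr <- sort(ctr)
      } else {
        ctr <- sort(round(stats::runif(ne, lo_h, hi_h)))
      }
      enh <- rbind(enh, data.frame(
        enh_id = "", chrom = cfg$chrom,
        start = ctr - floor(cfg$peak_width / 2),
        end = ctr - floor(cfg$peak_width / 2) + cfg$peak_width,
        hub = h, stringsAsFactors = FALSE))
    }
  }
  if (nrow(genes)) genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
  enh$enh_id <- sprintf("enh%04d", seq_len(nrow(enh)))

  # dominant enhancer per gene: nearest not-yet-assigned distal enhancer
  # (>= dominant_min_dist from the TSS) in the same hub; the distance floor
  # keeps the planted loop anchors well separated at the matrix resolution
  dominant <- rep(NA_character_, nrow(genes))
  taken <- character(0)
  enh_mid <- interval_midpoint(enh)
  for (gi in seq_len(nrow(genes))) {
    d_tss <- abs(enh_mid - genes$tss[gi])
    cand <- which(enh$hub == genes$hub[gi] & !(enh$enh_id %in% taken) &
                    d_tss >= cfg$dominant_min_dist)
    if (!length(cand)) {
      cand <- which(enh$hub == genes$hub[gi] & !(enh$enh_id %in% taken))
    }
    if (!length(cand)) cand <- which(enh$hub == genes$hub[gi])
    if (!length(cand)) next
    pick <- cand[which.min(d_tss[cand])]
    dominant[gi] <- enh$enh_id[pick]
    taken <- c(taken, enh$enh_id[pick])
  }

  shared <- stats::rlnorm(nrow(enh), cfg$signal_meanlog, cfg$signal_sdlog)
  boost <- ifelse(enh$enh_id %in% dominant, cfg$dominant_activity_mult, 1)
  atac_sig <- round(shared * boost * exp(stats::rnorm(nrow(enh), 0, 0.2)), 3)
  k27_sig <- round(shared * boost * exp(stats::rnorm(nrow(enh), 0, 0.2)), 3)
  jit <- function() round(stats::rnorm(nrow(enh), 0, cfg$peak_width / 10))
  atac <- data.frame(chrom = enh$chrom, start = pmax(0, enh$start + jit()),
                     name = paste0(enh$enh_id, "_atac"), signal = atac_sig,
                     stringsAsFactors = FALSE)
  atac$end <- atac$start + cfg$peak_width
  atac <- sort_intervals(atac[c("chrom", "start", "end", "name", "signal")])
  k27 <- data.frame(chrom = enh$chrom, start = pmax(0, enh$start + jit()),
                    name = paste0(enh$enh_id, "_k27"), signal = k27_sig,
                    stringsAsFactors = FALSE)
  k27$end <- k27$start + cfg$peak_width
  k27 <- sort_intervals(k27[c("chrom", "start", "end", "name", "signal")])

  n_extra <- round(cfg$ctcf_within_fraction * cfg$n_enhancers)
  ctcf_pos <- c(bounds * cfg$resolution,
                if (n_extra > 0)
                  round(stats::runif(n_extra, cfg$boundary_margin,
                                     cfg$chrom_length - cfg$boundary_margin)))
  ctcf <- data.frame(chrom = cfg$chrom, start = pmax(0, ctcf_pos - 100),
                     end = ctcf_pos + 100,
                     name = c(sprintf("ctcf_boundary_%02d",
                                      seq_along(bounds)),
                              if (n_extra > 0)
                                sprintf("ctcf_within_%03d", seq_len(n_extra))),
                     signal = 1, stringsAsFactors = FALSE)
  ctcf <- sort_intervals(ctcf)

  truth <- list(
    boundary_bins = bounds,
    hubs = lapply(seq_len(n_hubs), function(h) list(
      hub = h,
      gene_ids = genes$gene_id[genes$hub == h],
      enh_ids = enh$enh_id[enh$hub == h])),
    enhancers = enh,
    dominant = stats::setNames(dominant, genes$gene_id),
    config = cfg)
  list(genes = genes[c("gene_id", "chrom", "tss", "strand", "expression")],
       atac = atac, h3k27ac = k27, ctcf_sites = ctcf, truth = truth,
       genes_full = genes)
}

# planted loops: gene TSS bin x dominant enhancer bin, separation >= 2 bins
planted_loops <- function(genome, cfg) {
  genes <- genome$genes_full
  enh <- genome$truth$enhancers
  dom <- genome$truth$dominant
  if (!nrow(genes)) return(empty_loops())
  emid <- interval_midpoint(enh)[match(dom[genes$gene_id], enh$enh_id)]
  b_g <- floor(genes$tss / cfg$resolution)
  b_e <- floor(emid / cfg$resolution)
  keep <- !is.na(b_e) & abs(b_e - b_g) >= 2
  if (!any(keep)) return(empty_loops())
  lo <- pmin(b_g[keep], b_e[keep])
  hi <- pmax(b_g[keep], b_e[keep])
  loops <- data.frame(chrom1 = cfg$chrom, start1 = lo * cfg$resolution,
                      end1 = (lo + 1) * cfg$resolution,
                      chrom2 = cfg$chrom, start2 = hi * cfg$resolution,
                      end2 = (hi + 1) * cfg$resolution,
                      score = cfg$loop_strength, stringsAsFactors = FALSE)
  canonicalize_loops(unique(loops))
}

#' Simulate a contact matrix for one condition
#'
#' Expected counts follow
#' `mu(i, j) = contact_scale * max(|i - j|, 1)^(-alpha)`, scaled by the
#' insulation factor when i and j fall in different TADs and by
#' `loop_strength` at planted loop bin pairs. Realized counts are
#' negative-binomial around `mu` (or exactly `mu` when
#' `noise_dispersion = 0`). The KO condition substitutes `ko_insulation`
#' and removes loops anchored within one bin of a planted boundary.
#'
#' @param config A `sim_config`.
#' @param genome Output of [simulate_genome()] on the same config (supplies
#'   planted loop positions); when `NULL` a loop-free matrix is generated.
#' @param condition `"control"` or `"ko"`.
#' @return List: `cm` (a `contact_matrix`), `loops` (the planted loops
#'   present in this condition).
#' @export
simulate_contacts <- function(config, genome = NULL,
                              condition = c("control", "ko")) {
  cfg <- validate_config(config)
  condition <- match.arg(condition)
  # one noise stream shared by both conditions (paired design): counts are
  # drawn by inverse CDF from common uniforms, so the KO matrix differs
  # from the control only through the planted mechanism, exactly as a
  # perturbation of the same nuclei would
  set.seed(cfg$seed + 1L)
  n_bins <- as.integer(cfg$chrom_length / cfg$resolution)
  bounds <- planted_boundaries(cfg)
  ins <- if (condition == "control") cfg$insulation else cfg$ko_insulation

  loops <- if (is.null(genome)) empty_loops() else planted_loops(genome, cfg)
  if (condition == "ko" && nrow(loops)) {
    b1 <- loops$start1 / cfg$resolution
    b2 <- loops$start2 / cfg$resolution
    near_boundary <- vapply(seq_len(nrow(loops)), function(k) {
      any(abs(outer(c(b1[k], b2[k]), bounds, `-`)) <= 1)
    }, logical(1))
    loops <- loops[!near_boundary, , drop = FALSE]
  }

  max_off <- min(cfg$max_dist_bins, n_bins - 1)
  i <- unlist(lapply(0:max_off, function(d) seq.int(0, n_bins - 1 - d)),
              use.names = FALSE)
  j <- unlist(lapply(0:max_off, function(d) seq.int(d, n_bins - 1)),
              use.names = FALSE)
  d <- j - i
  mu <- cfg$contact_scale * pmax(d, 1)^(-cfg$decay_exponent)
  tad_i <- tad_of_bin(i, bounds)
  tad_j <- tad_of_bin(j, bounds)
  mu <- mu * ifelse(tad_i == tad_j, 1, ins)
  if (nrow(loops)) {
    key <- paste(loops$start1 / cfg$resolution, loops$start2 / cfg$resolution)
    at_loop <- paste(i, j) %in% key
    mu[at_loop] <- mu[at_loop] * cfg$loop_strength
  }
  counts <- if (cfg$noise_dispersion > 0) {
    u <- stats::runif(length(mu))
    stats::qnbinom(u, mu = mu, size = 1 / cfg$noise_dispersion)
  } else {
    mu
  }
  keep <- counts > 0
  cm <- contact_matrix(cfg$chrom, cfg$resolution, i[keep], j[keep],
                       counts[keep], n_bins = n_bins,
                       normalization = "synthetic")
  list(cm = cm, loops = loops)
}

#' Simulate gene and enhancer differential tables
#'
#' Each hub draws a shared standard-normal factor; every member's log2 fold
#' change is `scale * (sqrt(rho) * factor + sqrt(1 - rho) * noise)`, so the
#' expected correlation between hub-mates is `rho`. A `strong_fraction` of
#' hubs uses `strong_rho` and `strong_scale` instead, planting the
#' strong-effect subpopulation targeted by |log2fc| filters.
#'
#' @param config A `sim_config` (supplies rho, strong settings and the
#'   seed).
#' @param truth Truth list from [simulate_genome()] (hub memberships and
#'   enhancer loci). A hand-built list with the same shape works for
#'   stand-alone correlation studies.
#' @return List: `gene_lfc` (feature_id, log2fc), `enh_lfc` (feature_id,
#'   chrom, start, end, log2fc), `strong_hubs` (indices).
#' @export
simulate_differential <- function(config, truth) {
  cfg <- validate_config(config)
  set.seed(cfg$seed + 3L)
  hubs <- truth$hubs
  n_hubs <- length(hubs)
  n_strong <- round(cfg$strong_fraction * n_hubs)
  strong <- if (n_strong > 0) sort(sample(n_hubs, n_strong)) else integer(0)
  rho_h <- ifelse(seq_len(n_hubs) %in% strong, cfg$strong_rho,
                  cfg$coregulation_rho)
  scl_h <- ifelse(seq_len(n_hubs) %in% strong, cfg$strong_scale, 1)
  f_h <- stats::rnorm(n_hubs)
  gene_ids <- lapply(hubs, `[[`, "gene_ids")
  enh_ids <- lapply(hubs, `[[`, "enh_ids")
  ng <- lengths(gene_ids)
  ne <- lengths(enh_ids)
  # gene side loads +f, enhancer side sign(rho) * f, so the expected
  # gene-enhancer correlation within a hub equals rho (including sign)
  draw_side <- function(ids_per_hub, n_per_hub, factor_sign) {
    hub_of <- rep(seq_len(n_hubs), n_per_hub)
    n <- length(hub_of)
    lfc <- scl_h[hub_of] *
      (sqrt(abs(rho_h[hub_of])) * factor_sign[hub_of] * f_h[hub_of] +
         sqrt(1 - abs(rho_h[hub_of])) * stats::rnorm(n))
    data.frame(feature_id = unlist(ids_per_hub, use.names = FALSE),
               log2fc = lfc, stringsAsFactors = FALSE)
  }
  gene_lfc <- draw_side(gene_ids, ng, rep(1, n_hubs))
  enh_lfc <- draw_side(enh_ids, ne, ifelse(rho_h < 0, -1, 1))
  enh_tab <- truth$enhancers
  m <- match(enh_lfc$feature_id, enh_tab$enh_id)
  enh_lfc <- data.frame(feature_id = enh_lfc$feature_id,
                        chrom = enh_tab$chrom[m],
                        start = enh_tab$start[m], end = enh_tab$end[m],
                        log2fc = enh_lfc$log2fc, stringsAsFactors = FALSE)
  rownames(gene_lfc) <- NULL
  rownames(enh_lfc) <- NULL
  list(gene_lfc = gene_lfc, enh_lfc = enh_lfc, strong_hubs = strong)
}

#' Simulate a full paired-condition dataset
#'
#' Runs [simulate_genome()], [simulate_contacts()] for control and KO, and
#' [simulate_differential()]; optionally writes every file the pipeline
#' reads (narrowPeak, gene TSV, COO matrices, BEDPE loops, CTCF BED,
#' differential TSVs, truth JSON) to `outdir`.
#'
#' @param config A `sim_config`.
#' @param outdir Output directory; created if missing. `NULL` (default)
#'   keeps everything in memory.
#' @return List with all generated objects (`genes`, `atac`, `h3k27ac`,
#'   `ctcf_sites`, `contacts_control`, `contacts_ko`, `loops_control`,
#'   `loops_ko`, `gene_lfc`, `enh_lfc`, `truth`, and `paths` when written).
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  cfg <- validate_config(config)
  genome <- simulate_genome(cfg)
  ctl <- simulate_contacts(cfg, genome, "control")
  ko <- simulate_contacts(cfg, genome, "ko")
  diffs <- simulate_differential(cfg, genome$truth)
  out <- list(genes = genome$genes, atac = genome$atac,
              h3k27ac = genome$h3k27ac, ctcf_sites = genome$ctcf_sites,
              contacts_control = ctl$cm, contacts_ko = ko$cm,
              loops_control = ctl$loops, loops_ko = ko$loops,
              gene_lfc = diffs$gene_lfc, enh_lfc = diffs$enh_lfc,
              truth = genome$truth, config = cfg)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_peaks_narrowpeak(out$atac, p("atac.narrowPeak"))
    write_peaks_narrowpeak(out$h3k27ac, p("h3k27ac.narrowPeak"))
    write_gene_table(out$genes, p("genes.tsv"))
    write_bed(out$ctcf_sites, p("ctcf_sites.bed"))
    write_contact_matrix(out$contacts_control, p("contacts_control.coo"))
    write_contact_matrix(out$contacts_ko, p("contacts_ko.coo"))
    write_bedpe(out$loops_control, p("loops_control.bedpe"))
    write_bedpe(out$loops_ko, p("loops_ko.bedpe"))
    write_differential_table(out$gene_lfc, p("gene_lfc.tsv"))
    write_differential_table(out$enh_lfc, p("enh_lfc.tsv"))
    truth_json <- out$truth
    truth_json$config <- unclass(truth_json$config)
    jsonlite::write_json(truth_json, p("truth.json"), auto_unbox = TRUE,
                         digits = NA)
    out$paths <- vapply(c("atac.narrowPeak", "h3k27ac.narrowPeak",
                          "genes.tsv", "ctcf_sites.bed",
                          "contacts_control.coo", "contacts_ko.coo",
                          "loops_control.bedpe", "loops_ko.bedpe",
                          "gene_lfc.tsv", "enh_lfc.tsv", "truth.json"),
                        p, character(1))
  }
  out
}

#' Write peaks in the 10-column narrowPeak dialect
#' @param peaks Peak data frame (`chrom`, `start`, `end`, `name`, `signal`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_narrowpeak <- function(peaks, path) {
  validate_intervals(peaks, "peak")
  peaks <- sort_intervals(peaks)
  name <- if ("name" %in% names(peaks)) {
    ifelse(is.na(peaks$name), ".", peaks$name)
  } else "."
  out <- paste(peaks$chrom, fmt_pos(peaks$start), fmt_pos(peaks$end), name,
               0, ".", peaks$signal, -1, -1,
               fmt_pos(floor((peaks$end - peaks$start) / 2)), sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Recovery of planted hubs by a set of called CRHs
#'
#' Maps every recovered element to its best-overlapping planted enhancer and
#' scores, for each planted hub, the best member-set Jaccard achieved by any
#' recovered hub (genes matched by id, elements by locus).
#'
#' @param crhs A `crh_set` recovered from synthetic data.
#' @param truth Truth list from [simulate_genome()].
#' @return List: `per_hub` (Jaccard per planted hub) and `mean_jaccard`.
#' @export
planted_hub_recovery <- function(crhs, truth) {
  mem <- crhs$membership
  el <- mem[mem$member_type == "element", , drop = FALSE]
  # a recovered element represents every planted enhancer locus it covers
  # (adjacent planted enhancers can merge into one candidate)
  hits <- overlap_pairs(el, truth$enhancers)
  hub_ids <- unique(mem$hub_id)
  recovered_sets <- lapply(hub_ids, function(h) {
    rows <- which(el$hub_id == h)
    genes <- mem$member_id[mem$hub_id == h & mem$member_type == "gene"]
    els <- truth$enhancers$enh_id[hits$subject[hits$query %in% rows]]
    n_unmatched <- sum(!rows %in% hits$query)
    if (n_unmatched) {
      els <- c(els, paste0("unmatched_", seq_len(n_unmatched)))
    }
    unique(c(genes, els))
  })
  per_hub <- vapply(truth$hubs, function(ph) {
    planted <- c(ph$gene_ids, ph$enh_ids)
    if (!length(planted)) return(NA_real_)
    best_j <- 0
    for (rs in recovered_sets) {
      inter <- length(intersect(planted, rs))
      j <- inter / (length(planted) + length(rs) - inter)
      if (j > best_j) best_j <- j
    }
    best_j
  }, numeric(1))
  list(per_hub = per_hub, mean_jaccard = mean(per_hub, na.rm = TRUE))
}
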