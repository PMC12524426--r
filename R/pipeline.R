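# End-to-end composition: candidates -> activities -> ABC scores ->
# thresholded pairs -> hubs -> TADs -> hub/TAD classification, with the
# optional two-condition comparison and differential-correlation blocks.
# Every run writes a manifest of resolved parameters and input digests.

#' Run the single- or two-condition CRH pipeline
#'
#' Inputs are file paths; condition B and differential tables are optional.
#' When condition B is supplied the comparison block (shared pairs, score
#' distributions, hub comparison, site enrichment, KO TAD classification
#' against the condition-A TADs) is added; when differential tables are
#' supplied the correlation block is added.
#'
#' @param atac,h3k27ac Paths to narrowPeak files (condition A / control).
#' @param genes Path to the gene table TSV.
#' @param contacts Path to the condition-A COO contact matrix.
#' @param resolution Contact-matrix resolution in bp.
#' @param atac_b,h3k27ac_b,contacts_b Optional condition-B inputs (condition
#'   B reuses the condition-A peak files when only `contacts_b` is given,
#'   mirroring a perturbation that rewires contacts but not peaks).
#' @param ctcf_sites Optional BED of sites for the hub enrichment test.
#' @param gene_lfc,enh_lfc Optional differential TSVs.
#' @param loops Optional BEDPE for APA.
#' @param outdir Output directory for tables, JSON summary and manifest.
#' @param window,cutoff,expression_floor,min_width,max_width,promoter_margin
#'   ABC parameters (see [compute_abc_scores()], [define_candidates()]).
#' @param di_window,magnitude_quantile,min_tad_size TAD parameters.
#' @param flank_bins APA flank (used when `loops` is given).
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic).
#'
#' @return The summary list, invisibly; files under `outdir`.
#' @export
run_pipeline <- function(atac, h3k27ac, genes, contacts, resolution = 1e4,
                         atac_b = NULL, h3k27ac_b = NULL, contacts_b = NULL,
                         ctcf_sites = NULL, gene_lfc = NULL, enh_lfc = NULL,
                         loops = NULL, outdir = "crhub_out",
                         window = 5e6, cutoff = 0.01,
                         expression_floor = 0.5, min_width = 500,
                         max_width = 10000, promoter_margin = 500,
                         di_window = 2e6, magnitude_quantile = 0.8,
                         min_tad_size = 1e5, flank_bins = 10, seed = 1L) {
  inputs <- c(atac = atac, h3k27ac = h3k27ac, genes = genes,
              contacts = contacts, atac_b = atac_b, h3k27ac_b = h3k27ac_b,
              contacts_b = contacts_b, ctcf_sites = ctcf_sites,
              gene_lfc = gene_lfc, enh_lfc = enh_lfc, loops = loops)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  params <- list(resolution = resolution, window = window, cutoff = cutoff,
                 expression_floor = expression_floor, min_width = min_width,
                 max_width = max_width, promoter_margin = promoter_margin,
                 di_window = di_window,
                 magnitude_quantile = magnitude_quantile,
                 min_tad_size = min_tad_size, flank_bins = flank_bins,
                 seed = seed)

  gene_tab <- read_gene_table(genes)
  promoters <- promoter_windows(gene_tab, promoter_margin)

  run_condition <- function(atac_path, k27_path, contacts_path) {
    atac_peaks <- read_narrowpeak(atac_path)
    k27_peaks <- read_narrowpeak(k27_path)
    cm <- read_contact_matrix(contacts_path, resolution)
    el <- define_candidates(atac_peaks, k27_peaks, promoters,
                            min_width = min_width, max_width = max_width)
    el <- compute_activity(el, atac_peaks, k27_peaks)
    all_pairs <- compute_abc_scores(el, gene_tab, cm, window = window,
                                    expression_floor = expression_floor)
    pairs <- threshold_pairs(all_pairs, cutoff)
    crhs <- build_crhs(pairs)
    track <- directionality_index(cm, di_window)
    tads <- call_tads(track, magnitude_quantile, min_tad_size)
    list(cm = cm, elements = el, all_pairs = all_pairs, pairs = pairs,
         crhs = crhs, track = track, tads = tads)
  }

  a <- run_condition(atac, h3k27ac, contacts)
  summary <- list(parameters = params)
  summary$condition_a <- list(
    n_candidates = nrow(a$elements),
    n_pairs = nrow(a$pairs),
    n_distal_elements = attr(a$pairs, "n_elements"),
    n_linked_genes = attr(a$pairs, "n_genes"),
    hub_stats = hub_stats(a$crhs),
    n_tads = nrow(a$tads),
    crh_tad_fractions = as.list(classify_crh_tads(a$crhs, a$tads)$fractions))

  write_pairs_tsv(a$pairs, file.path(outdir, "pairs_a.tsv"))
  write_hubs_tsv(a$crhs, outdir, "a")
  write_bed(a$tads, file.path(outdir, "tads_a.bed"))
  write_di_bedgraph(a$track, file.path(outdir, "di_a.bedgraph"))
  write_longrange(pairs_to_loops(a$pairs), file.path(outdir,
                                                     "pairs_a.longrange"))

  two_cond <- !is.null(contacts_b)
  if (two_cond) {
    b <- run_condition(atac_b %||% atac, h3k27ac_b %||% h3k27ac, contacts_b)
    summary$condition_b <- list(
      n_candidates = nrow(b$elements),
      n_pairs = nrow(b$pairs),
      n_distal_elements = attr(b$pairs, "n_elements"),
      n_linked_genes = attr(b$pairs, "n_genes"),
      hub_stats = hub_stats(b$crhs),
      n_tads = nrow(b$tads),
      crh_tad_fractions_vs_a =
        as.list(classify_crh_tads(b$crhs, a$tads)$fractions))
    cmp <- compare_hubs(a$crhs, b$crhs)
    summary$comparison <- list(
      shared_pairs = shared_pairs(a$pairs, b$pairs),
      scores = score_distribution_report(a$pairs, b$pairs),
      hub_labels = as.list(cmp$label_counts),
      simple_merge = cmp$simple_merge)
    if (!is.null(ctcf_sites)) {
      sites <- read_narrowpeak(ctcf_sites)
      enr <- site_enrichment(a$crhs, b$crhs, sites)
      summary$comparison$site_enrichment <-
        list(odds_ratio = enr$odds_ratio, p_value = enr$p_value,
             table = as.vector(enr$table),
             haldane_corrected = enr$haldane_corrected)
    }
    write_pairs_tsv(b$pairs, file.path(outdir, "pairs_b.tsv"))
    write_hubs_tsv(b$crhs, outdir, "b")
    write_comparison_tsv(cmp, file.path(outdir, "hub_comparison.tsv"))
  }

  if (!is.null(gene_lfc) && !is.null(enh_lfc)) {
    g_lfc <- read_differential_table(gene_lfc)
    e_lfc <- read_differential_table(enh_lfc)
    summary$differential <- list(
      eg_correlation = eg_change_correlation(a$pairs, g_lfc, e_lfc),
      eg_correlation_filtered =
        tryCatch(eg_change_correlation(a$pairs, g_lfc, e_lfc,
                                       min_abs_lfc = 0.5),
                 error = function(e) NULL),
      hub_coregulation = hub_coregulation(a$crhs, g_lfc, e_lfc))
  }

  if (!is.null(loops)) {
    apa <- aggregate_loops(a$cm, read_bedpe(loops), flank_bins = flank_bins)
    summary$apa <- list(apa_score = apa$apa_score, z_score = apa$z_score,
                        n_loops_used = apa$n_loops_used)
    write_apa_matrix(apa, file.path(outdir, "apa_matrix.tsv"))
  }

  manifest <- list(command = "run_pipeline", parameters = params,
                   package_version =
                     as.character(utils::packageVersion("crhub")),
                   inputs = as.list(inputs),
                   input_md5 = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Write a pair table as TSV
#' @param pairs Pair table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pair table written by [write_pairs_tsv()]
#' @param path Path to the TSV.
#' @return Pair data frame.
#' @export
read_pairs_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

write_hubs_tsv <- function(crhs, outdir, tag) {
  utils::write.table(crhs$membership,
                     file.path(outdir, sprintf("hub_members_%s.tsv", tag)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(crhs$edges,
                     file.path(outdir, sprintf("hub_edges_%s.tsv", tag)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

write_comparison_tsv <- function(cmp, path) {
  utils::write.table(cmp$labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

# scored pairs as loops (element interval <-> TSS bin-ish point) for
# longrange export
pairs_to_loops <- function(pairs) {
  if (!nrow(pairs)) return(empty_loops())
  canonicalize_loops(data.frame(
    chrom1 = pairs$chrom, start1 = pairs$start, end1 = pairs$end,
    chrom2 = pairs$chrom, start2 = pairs$tss, end2 = pairs$tss + 1,
    score = signif(pairs$abc_score, 4), stringsAsFactors = FALSE))
}
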