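# End-to-end orchestration on synthetic inputs: annotate -> quantify ->
# classify -> compare, plus the tissue, microarray-screen, enrichment and
# decay stages, summarized in one machine-readable report.

#' Default pipeline configuration
#'
#' Thresholds default to the published values: sensitive = at least 3-fold
#' with Z-score p < 0.01, neutral = less than 2-fold, proximal pA at least
#' 20 b from the distal boundary, small-ratio cut 0.25, shortening cut 0.5x,
#' SPM > 0.9 specific / SPM > 0.3 and CTM > 0.9 selective, gene sets of 15 to
#' 5000 members, leading-edge selection at 5 sets.
#'
#' @param seed Integer seed driving every stage.
#' @return Named list of stage parameters and thresholds.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    n_genes = 500,
    pa_fraction = 0.8,
    reads_per_gene = 200,
    n_sensitive = 50,
    effect_range = c(3, 8),
    pi_base_range = c(0.15, 0.95),
    pi_shift = 0.3,
    thresholds = list(
      fc_sensitive = 3, p_sensitive = 0.01, fc_neutral = 2,
      min_pa_distance = 20, small_ratio = 0.25, shortening = 0.5,
      spm_specific = 0.9, spm_selective = 0.3, ctm_selective = 0.9,
      set_size = c(15, 5000), leading_edge_min = 5),
    tissue = list(n_genes = 300, n_specific = 30, n_selective = 30,
                  noise_sdlog = 0.3),
    screen = list(n_genes = 200, n_shift = 60, ratio_ctr = 0.15,
                  ratio_kd = 0.6, ratio_null = 0.6),
    gsea = list(n_sets = 12, set_size = 30, n_planted = 2, n_perm = 200),
    decay = list(classes = c(decreased = 6, steady = 2, stable = Inf),
                 n_per_class = 150, timepoints = c(3, 6, 12)))
}

#' Run the full synthetic-data analysis pipeline
#'
#' Stages: (1) simulate gene models and polyA sites, build the split
#' annotation; (2) simulate two-condition reads with planted sensitive genes
#' whose long-isoform fraction is lowered, count, compute d3'UTR ratios,
#' classify sensitivity, run the size-matched ratio comparison and the
#' small-ratio concordance; (3) tissue-restriction classification on a
#' planted tissue matrix; (4) probe-level microarray screen with the
#' imbalance test; (5) classic GSEA with leading-edge summary and d3'UTR
#' miRNA-site filtering; (6) decay time-course group comparison. Identical
#' config (and seed) reproduces the summary byte-identically.
#'
#' @param config See [default_pipeline_config()].
#' @param out_dir Optional output directory for `summary.json` and stage
#'   tables.
#' @return The summary list, invisibly; also written as JSON when `out_dir`
#'   is given. The JSON string is attached as attribute `"json"`.
#' @export
run_apa_analysis <- function(config = default_pipeline_config(),
                             out_dir = NULL) {
  th <- config$thresholds
  seed <- config$seed

  ## 1. annotation -----------------------------------------------------------
  ann <- simulate_annotation(n_genes = config$n_genes,
                             pa_fraction = config$pa_fraction, seed = seed)
  split <- build_split_annotation(ann$models, ann$pa_sites,
                                  min_distance = th$min_pa_distance)

  ## 2. two-condition quantification ----------------------------------------
  set.seed(seed + 1)
  ids <- ann$truth$gene_id
  sensitive_ids <- sort(sample(ids, config$n_sensitive))
  effect <- stats::setNames(rep(1, length(ids)), ids)
  effect[sensitive_ids] <- stats::runif(config$n_sensitive,
                                        config$effect_range[1],
                                        config$effect_range[2])
  # shortening is cell-intrinsic in this world: sensitive genes carry a lower
  # long-isoform fraction than neutral genes, in both conditions; the
  # condition effect touches expression only
  pi_gene <- stats::setNames(
    stats::runif(length(ids), config$pi_base_range[1],
                 config$pi_base_range[2]), ids)
  pi_gene[sensitive_ids] <- pmax(pi_gene[sensitive_ids] - config$pi_shift,
                                 0.05)
  depth <- stats::setNames(
    stats::rlnorm(length(ids), log(config$reads_per_gene), 0.6), ids)
  reads_ko <- simulate_reads(ann, pi = pi_gene, reads_per_gene = depth,
                             seed = seed + 2, sample_id = "ko")
  reads_wt <- simulate_reads(ann, pi = pi_gene,
                             reads_per_gene = depth * effect,
                             seed = seed + 3, sample_id = "wt")
  tab_ko <- count_contained_reads(reads_ko, split$features, sample_id = "ko")
  tab_wt <- count_contained_reads(reads_wt, split$features, sample_id = "wt")
  ratios_ko <- compute_d3utr_ratios(tab_ko, split$features)
  ratios_wt <- compute_d3utr_ratios(tab_wt, split$features)
  de <- differential_expression(gene_level_counts(tab_ko, split$features),
                                gene_level_counts(tab_wt, split$features))
  de <- classify_aire_sensitivity(de, fc_sensitive = th$fc_sensitive,
                                  p_sensitive = th$p_sensitive,
                                  fc_neutral = th$fc_neutral)
  called_sensitive <- de$gene_id[de$label == "sensitive"]
  called_neutral <- de$gene_id[de$label == "neutral"]
  rw <- stats::setNames(ratios_wt$ratio, ratios_wt$gene_id)
  test_vals <- rw[intersect(called_sensitive, names(rw))]
  test_vals <- test_vals[!is.na(test_vals)]
  ctrl_vals <- rw[intersect(called_neutral, names(rw))]
  ctrl_vals <- ctrl_vals[!is.na(ctrl_vals)]
  fc_all <- stats::setNames(de$fc, de$gene_id)
  cmp <- size_matched_wilcoxon(test_vals, ctrl_vals, fc_all)
  rk <- stats::setNames(ratios_ko$ratio, ratios_ko$gene_id)
  both <- intersect(names(rw)[!is.na(rw)], names(rk)[!is.na(rk)])
  low_wt <- both[rw[both] < th$small_ratio]
  high_wt <- both[rw[both] > th$small_ratio]
  concordance <- list(
    low = if (length(low_wt)) mean(rk[low_wt] < th$small_ratio) else NA,
    high = if (length(high_wt)) mean(rk[high_wt] > th$small_ratio) else NA)

  ## 3. tissue restriction ---------------------------------------------------
  tis <- simulate_tissue_matrix(
    n_genes = config$tissue$n_genes, n_specific = config$tissue$n_specific,
    n_selective = config$tissue$n_selective,
    noise_sdlog = config$tissue$noise_sdlog, seed = seed + 4)
  tis_called <- classify_tissue_matrix(tis$matrix,
                                       spm_specific = th$spm_specific,
                                       spm_selective = th$spm_selective,
                                       ctm_selective = th$ctm_selective)
  tis_called <- pick_peripheral_tissue(tis_called, seed = seed + 5)
  planted <- tis$truth$label != "unassigned"
  tissue_recovery <- mean(tis_called$label[planted] ==
                          tis$truth$label[planted])

  ## 4. microarray screen ----------------------------------------------------
  scr_genes <- split$genes$gene_id[split$genes$has_pa]
  scr_genes <- scr_genes[seq_len(min(config$screen$n_genes,
                                     length(scr_genes)))]
  scr_feats <- split$features[split$features$gene_id %in% scr_genes, ]
  set.seed(seed + 6)
  shifted <- sort(sample(scr_genes, config$screen$n_shift))
  r_ctr <- stats::setNames(rep(config$screen$ratio_ctr,
                               length(shifted)), shifted)
  r_kd <- stats::setNames(rep(config$screen$ratio_kd,
                              length(shifted)), shifted)
  probes_cand <- simulate_probes(scr_feats, ratio_a = r_ctr, ratio_b = r_kd,
                                 seed = seed + 7)
  probes_null <- simulate_probes(scr_feats, ratio_a = numeric(0),
                                 ratio_b = numeric(0), seed = seed + 8)
  prep <- function(p) {
    p <- filter_expressed_probes(p, c("a_1", "a_2", "b_1", "b_2"))
    assign_probe_region(p, scr_feats)
  }
  screen_cand <- array_screen(prep(probes_cand), c("a_1", "a_2"),
                              c("b_1", "b_2"))
  screen_null <- array_screen(prep(probes_null), c("a_1", "a_2"),
                              c("b_1", "b_2"))
  imb <- ratio_imbalance_test(screen_cand, screen_null)
  shorten_class <- classify_shortening(
    stats::setNames(screen_cand$ratio_a, screen_cand$gene_id),
    stats::setNames(screen_cand$ratio_b, screen_cand$gene_id),
    decrease_cut = th$shortening)

  ## 5. enrichment -----------------------------------------------------------
  metric <- stats::setNames(log2(de$fc), de$gene_id)
  set.seed(seed + 9)
  universe <- names(rank_metric(metric))
  sets <- list()
  for (i in seq_len(config$gsea$n_sets - config$gsea$n_planted))
    sets[[sprintf("mir_null_%02d", i)]] <-
      sample(universe, config$gsea$set_size)
  top <- top_fraction_set(metric, 0.3)
  for (i in seq_len(config$gsea$n_planted))
    sets[[sprintf("mir_planted_%02d", i)]] <-
      sample(top, config$gsea$set_size)
  gsea <- gsea_classic(metric, sets, n_perm = config$gsea$n_perm,
                       seed = seed + 10, set_range = th$set_size)
  le <- leading_edge_summary(gsea, min_count = th$leading_edge_min)
  set.seed(seed + 11)
  d3_feats <- split$features[split$features$kind == "d3utr", ]
  site_genes <- sample(d3_feats$gene_id,
                       min(100, nrow(d3_feats)))
  site_rows <- d3_feats[match(site_genes, d3_feats$gene_id), ]
  sites <- data.frame(mirna = sprintf("miR-%02d", seq_along(site_genes) %% 8),
                      gene_id = site_genes, chrom = site_rows$chrom,
                      start = site_rows$start + 10,
                      end = site_rows$start + 17)
  mirna <- filter_d3utr_mirna_sites(sites, split$features,
                                    gene_subset = sensitive_ids)

  ## 6. decay ----------------------------------------------------------------
  dec <- simulate_decay(classes = config$decay$classes,
                        n_per_class = config$decay$n_per_class,
                        timepoints = config$decay$timepoints,
                        seed = seed + 12)
  rel <- decay_relative_expression(dec$treated, dec$control)
  cls <- stats::setNames(dec$truth$class, dec$truth$gene_id)
  dcmp <- compare_decay_groups(rel, cls, groups = c("decreased", "steady"))

  ## summary -----------------------------------------------------------------
  summary <- list(
    thresholds = th,
    annotation = list(
      n_genes = config$n_genes,
      n_with_pa = sum(split$genes$has_pa),
      n_features = nrow(split$features)),
    quantify = list(
      library_wt = tab_wt$library_size, library_ko = tab_ko$library_size,
      n_ratios_wt = sum(!is.na(ratios_wt$ratio)),
      n_ratios_ko = sum(!is.na(ratios_ko$ratio))),
    sensitivity = list(
      n_called_sensitive = length(called_sensitive),
      n_called_neutral = length(called_neutral),
      recovery_sensitivity =
        mean(sensitive_ids %in% called_sensitive),
      false_discovery =
        if (length(called_sensitive) == 0) 0
        else mean(!(called_sensitive %in% sensitive_ids))),
    ratio_comparison = list(
      median_sensitive = stats::median(cmp$test),
      median_neutral = stats::median(cmp$control),
      n_matched = length(cmp$control), p = cmp$p),
    small_ratio_concordance = concordance,
    tissue = list(
      n_called_specific = sum(tis_called$label == "specific"),
      n_called_selective = sum(tis_called$label == "selective"),
      planted_recovery = tissue_recovery),
    screen = list(
      counts = as.list(stats::setNames(as.vector(imb$table),
                                       c("cand_inc", "ctrl_inc",
                                         "cand_dec", "ctrl_dec"))),
      chisq = imb$statistic, p = imb$p, stars = imb$stars,
      n_shortened = sum(shorten_class == "decreased", na.rm = TRUE)),
    enrichment = list(
      n_sets_tested = nrow(gsea),
      top_set = gsea$set_id[which.min(gsea$fdr_q)],
      n_significant = sum(gsea$fdr_q < 0.05, na.rm = TRUE),
      n_leading_selected = sum(le$selected)),
    mirna_sites = list(proportion_sensitive_with_d3utr_site =
                         mirna$proportion),
    decay = list(
      timepoints = config$decay$timepoints,
      p = dcmp$tests$p,
      median_decreased =
        dcmp$medians$rel_expr[dcmp$medians$group == "decreased"],
      median_steady =
        dcmp$medians$rel_expr[dcmp$medians$group == "steady"]))
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, na = "null")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(json, file.path(out_dir, "summary.json"))
    write_split_gtf(split$features, file.path(out_dir, "split.gtf"))
    write_tsv(de, file.path(out_dir, "de.tsv"))
    write_tsv(ratios_wt, file.path(out_dir, "ratios_wt.tsv"))
    write_tsv(ratios_ko, file.path(out_dir, "ratios_ko.tsv"))
    write_tsv(tis_called, file.path(out_dir, "tissue_labels.tsv"))
    write_tsv(screen_cand, file.path(out_dir, "screen.tsv"))
    gtab <- gsea[, c("set_id", "size", "es", "nes", "p", "fdr_q")]
    write_tsv(gtab, file.path(out_dir, "gsea.tsv"))
    write_tsv(dcmp$tests, file.path(out_dir, "decay_tests.tsv"))
  }
  attr(summary, "json") <- as.character(json)
  invisible(summary)
}
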