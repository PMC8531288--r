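# End-to-end pipeline on synthetic data: simulate -> compartment QC ->
# normalize/HVG/PCA/cluster -> bulk DE signature -> per-cell scoring and
# median-split classification -> stem cluster + proportion dynamics ->
# stage trend -> survival stratification -> cytokine-receptor cross-talk.

#' Run the full stem-cell-dynamics pipeline on synthetic data
#'
#' Executes every stage of the analysis on data from the package's
#' generators, writing all result tables to `out_dir` as CSV/GMT/JSON.
#' Given the same configuration and seed, two runs produce byte-identical
#' output files.
#'
#' @param config Path to a YAML/JSON run configuration, or an equivalent
#'   nested list. Default: the configuration shipped with the package
#'   (`system.file("extdata", "default_config.yaml", package = "stemdyn")`).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the configuration's global seed.
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "default_config.yaml", package = "stemdyn")
  }
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim_args <- cfg$simulate %||% list()
  if (!is.null(sim_args$cells_per_stage)) {
    sim_args$cells_per_stage <- unlist(sim_args$cells_per_stage)
  }
  for (f in c("epithelial_fraction", "cancer_fraction_by_stage", "depth_mean",
              "mito_fraction")) {
    if (!is.null(sim_args[[f]])) sim_args[[f]] <- unlist(sim_args[[f]])
  }
  sim_cfg <- do.call(sim_config, c(sim_args, list(seed = cfg$seed)))
  sim <- simulate_single_cell(sim_cfg)
  stages <- stats::setNames(sim$cells$stage, sim$cells$cell_id)

  ## --- compartment-specific QC -------------------------------------------
  metrics <- compute_qc_metrics(sim$counts, mito_prefix = sim_cfg$mito_prefix)
  comp <- stats::setNames(sim$cells$compartment, sim$cells$cell_id)
  kept <- character()
  qc_summary <- list()
  for (cp in c("epithelial", "immune")) {
    sub <- metrics[comp[metrics$cell_id] == cp, , drop = FALSE]
    res <- filter_cells(sub, qc_criteria(cp))
    kept <- c(kept, res$kept)
    qc_summary[[cp]] <- list(n_input = res$n_input, n_kept = res$n_kept,
                             removed_by = as.list(res$removed_by))
  }
  kept <- intersect(metrics$cell_id, kept)  # restore matrix order
  write_table(metrics, file.path(out_dir, "qc_metrics.csv"))
  write_table(data.frame(cell_id = kept, stringsAsFactors = FALSE),
              file.path(out_dir, "qc_kept.csv"))

  ## --- normalize, embed, cluster -----------------------------------------
  pp <- cfg$preprocess %||% list()
  counts_f <- sim$counts[, kept, drop = FALSE]
  norm <- lognormalize(counts_f, scale_factor = pp$scale_factor %||% 10000)
  hvgs <- select_hvgs(norm, n = pp$n_hvgs %||% 3000)
  scaled <- scale_genes(norm, hvgs, clip = pp$clip %||% 10)
  emb <- run_pca(scaled, n_components = pp$n_pcs %||% 50)
  clusters <- cluster_cells(emb,
                            resolution = pp$resolution %||% 0.4,
                            k_neighbors = pp$k_neighbors %||% 20,
                            seed = child_seed(cfg$seed, 11L))
  write_table(data.frame(cell_id = names(clusters),
                         cluster = as.character(clusters),
                         stringsAsFactors = FALSE),
              file.path(out_dir, "cluster_labels.csv"))
  write_table(data.frame(cell_id = rownames(emb$coordinates),
                         emb$coordinates, check.names = FALSE,
                         stringsAsFactors = FALSE),
              file.path(out_dir, "embedding.csv"))

  ## --- bulk DE -> cancer signature ---------------------------------------
  bk <- cfg$bulk %||% list()
  bulk <- simulate_bulk(sim_cfg,
                        n_per_group = bk$n_per_group %||% 3,
                        fold_change = bk$fold_change %||% 4,
                        dispersion = bk$dispersion %||% 0.05)
  gates_cfg <- cfg$gates %||% list()
  gates <- de_gates(max_fdr = gates_cfg$max_fdr %||% 0.05,
                    min_fc_up = gates_cfg$min_fc_up %||% 1.5,
                    max_fc_down = gates_cfg$max_fc_down %||% 0.67)
  de <- bulk_de(bulk$counts, bulk$groups, treatment = "tumor")
  cancer_sig <- build_signature(de, gates, name = "cancer")
  write_table(de, file.path(out_dir, "de_bulk.csv"))
  write_gmt(list(cancer_sig), file.path(out_dir, "cancer_signature.gmt"))

  ## --- per-cell scoring and classification (epithelial compartment) ------
  epi <- kept[comp[kept] == "epithelial"]
  norm_epi <- norm[, epi, drop = FALSE]
  scores <- score_mean_diff(norm_epi, cancer_sig)
  classes <- classify_by_median(scores, signature_name = cancer_sig$name)
  write_table(scores, file.path(out_dir, "cancer_scores.csv"))
  write_table(classes, file.path(out_dir, "classification.csv"))

  ## --- stemness scoring and stem-cluster identification -------------------
  # The curated stemness gene set: the generator's stem-cell markers stand in
  # for the literature-derived stem signature.
  stem_sig_genes <- sim$truth$markers$stem
  stem_scores <- score_rank_es(norm_epi, stem_sig_genes)
  clusters_epi <- clusters[epi]
  stem_res <- identify_stem_cluster(stem_scores, clusters_epi)
  write_table(stem_res$ranking, file.path(out_dir, "stem_cluster_ranking.csv"))

  ## --- BCSCs and proportion dynamics -------------------------------------
  labels <- stats::setNames(classes$label, classes$cell_id)
  cancer_cells <- names(labels)[labels == "cancer"]
  in_top <- names(clusters_epi)[as.character(clusters_epi) == stem_res$top]
  bcsc <- intersect(cancer_cells, in_top)
  bcsc_labels <- stats::setNames(ifelse(names(labels) %in% bcsc, "bcsc", "other"),
                                 names(labels))
  proportions <- proportion_dynamics(bcsc_labels, stages[names(labels)],
                                     denominator = cancer_cells,
                                     target = "bcsc")
  write_table(proportions, file.path(out_dir, "bcsc_proportions.csv"))

  ## --- stage trend of the cancer score ------------------------------------
  trend <- grade_trend(scores$score, factor(stages[scores$cell_id],
                                            levels = unique(sim$cells$stage)))
  jsonlite::write_json(
    list(s = trend$s, var_s = trend$var_s, z = trend$z,
         p_value = trend$p_value, p_exact = trend$p_exact,
         medians = as.list(trend$medians)),
    file.path(out_dir, "stage_trend.json"), auto_unbox = TRUE, digits = NA)

  ## --- survival stratification --------------------------------------------
  ch <- cfg$cohort %||% list()
  cohort_sim <- simulate_cohort(n_subjects = ch$n_subjects %||% 200,
                                hazard_ratio = ch$hazard_ratio %||% 3,
                                censor_rate = ch$censor_rate %||% 0.2,
                                seed = child_seed(cfg$seed, 22L))
  strat <- stratify_by_signature(cohort_sim$expression, cohort_sim$signature,
                                 cohort_sim$cohort[, c("subject_id", "time", "event")])
  curves <- do.call(rbind, lapply(c("high", "low"), function(g) {
    sub <- strat[strat$group == g, ]
    cbind(group = g, km_curve(sub$time, sub$event))
  }))
  lr <- logrank_test(strat$time, strat$event, strat$group)
  write_table(strat, file.path(out_dir, "cohort_stratified.csv"))
  write_table(curves, file.path(out_dir, "survival_curves.csv"))
  jsonlite::write_json(list(statistic = lr$statistic, p_value = lr$p_value),
                       file.path(out_dir, "logrank.json"),
                       auto_unbox = TRUE, digits = NA)

  ## --- cytokine-receptor cross-talk ---------------------------------------
  pairs_path <- cfg$pairs_file %||%
    system.file("extdata", "cytokine_receptor_pairs.tsv", package = "stemdyn")
  pairs <- read_lr_pairs(pairs_path)
  summary <- pair_expression_summary(norm, clusters, pairs)
  # sources: the stem cluster; targets: clusters with an immune majority
  imm_frac <- tapply(comp[names(clusters)] == "immune", as.character(clusters), mean)
  targets <- names(imm_frac)[imm_frac > 0.5]
  ct_cfg <- cfg$crosstalk %||% list()
  flags <- if (length(targets)) {
    flag_interactions(summary,
                      source_clusters = stem_res$top,
                      target_clusters = targets,
                      min_fraction = ct_cfg$min_fraction %||% 0.1,
                      min_z = ct_cfg$min_z %||% 1)
  } else {
    warnf("run_pipeline: no immune-majority cluster; skipping cross-talk flags")
    NULL
  }
  write_table(summary$summary, file.path(out_dir, "crosstalk_summary.csv"))
  if (!is.null(flags)) write_table(flags, file.path(out_dir, "crosstalk_flags.csv"))

  jsonlite::write_json(
    list(seed = cfg$seed,
         n_cells = ncol(sim$counts),
         n_genes = nrow(sim$counts),
         qc = qc_summary,
         n_clusters = nlevels(clusters),
         signature = list(n_up = length(cancer_sig$up_genes),
                          n_down = length(cancer_sig$down_genes)),
         stem_cluster = stem_res$top,
         logrank_p = lr$p_value,
         trend_p = trend$p_value),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(sim = sim, metrics = metrics, kept = kept, norm = norm,
                 hvgs = hvgs, embedding = emb, clusters = clusters,
                 bulk = bulk, de = de, signature = cancer_sig,
                 scores = scores, classes = classes,
                 stem_scores = stem_scores, stem = stem_res,
                 bcsc = bcsc, proportions = proportions, trend = trend,
                 cohort = strat, curves = curves, logrank = lr,
                 crosstalk = list(summary = summary$summary, flags = flags)))
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
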