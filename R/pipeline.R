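#' Run the full biomarker-discovery pipeline from a configuration
#'
#' Executes every stage in order -- sampling campaign, accepted-model
#' aggregation, tissue enrichment, overlap enrichment, pathway-gene
#' clustering, pathway fitness with leave-one-out deltas, panel selection,
#' random-forest evaluation, pooled-t classifier, and network export --
#' writing each stage's output as plain text under `out_dir` together with a
#' provenance record (config hash, seed, package version). Outputs carry no
#' timestamps, so a rerun with the same configuration and seed is
#' byte-identical.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Recognised blocks: `out_dir`; either `synthetic` ([sim_config()]
#'   arguments) or `data` (paths `preclin_expr`, `preclin_response`,
#'   `clin_expr`, `clin_response`, `gene_sets`, plus `expr_orientation`);
#'   `campaign` ([campaign_config()] arguments); `enrichment` (`q_max`);
#'   `fitness` (`mode`, `tail_fraction`, `min_genes`, `p_max`); `panel`
#'   (`pct`, `p_max`); `evaluate` (`n_trees`, `n_seeds`, `seed`); `network`
#'   (`pct`); `aggregate` (`min_models`, an integer or `"auto"` for the upper
#'   97.5% Poisson tail of the observed per-gene selection density).
#' @param resume if TRUE, a stage whose output file already exists under
#'   `out_dir` is reloaded instead of recomputed (campaign stage only).
#' @return invisible list with all stage results.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("out_dir")) {
    if (is.null(config[[field]])) stop("config missing required field: ", field)
  }
  if (is.null(config$synthetic) && is.null(config$data))
    stop("config needs a 'synthetic' or 'data' block")
  if (!is.null(config$data)) {
    need <- c("preclin_expr", "preclin_response", "clin_expr",
              "clin_response", "gene_sets")
    miss <- setdiff(need, names(config$data))
    if (length(miss))
      stop("config data block missing: ", paste(miss, collapse = ", "))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  write_tsv <- function(d, f) {
    utils::write.table(format(d, digits = 17, trim = TRUE, scientific = NA),
                       path(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log_msg <- function(...) message("[pipeline] ", ...)

  # ---- inputs -------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    log_msg("generating synthetic dataset")
    sim <- do.call(sim_config, config$synthetic)
    data <- generate_dataset(sim)
    preclin_expr <- data$preclinical$expr
    preclin_response <- data$preclinical$response
    clin_expr <- data$clinical$expr
    clin_response <- data$clinical$response
    gene_sets <- data$gene_sets
  } else {
    d <- config$data
    orient <- if (is.null(d$expr_orientation)) "rows-are-genes"
              else d$expr_orientation
    preclin_expr <- read_expression_matrix(d$preclin_expr, orient)
    clin_expr <- read_expression_matrix(d$clin_expr, orient)
    preclin_response <- read_response_table(d$preclin_response)
    clin_response <- read_response_table(d$clin_response)
    both <- intersect_expression(preclin_expr, clin_expr)
    preclin_expr <- both$preclinical
    clin_expr <- both$clinical
    gene_sets <- read_gene_sets(d$gene_sets, colnames(preclin_expr))
    data <- NULL
  }

  # ---- campaign -----------------------------------------------------------
  camp_args <- config$campaign
  if (is.null(camp_args$n_samples)) stop("campaign block needs n_samples")
  camp_cfg <- do.call(campaign_config, camp_args)
  models_file <- path("models.jsonl")
  if (resume && file.exists(models_file)) {
    log_msg("resuming: loading accepted models from ", models_file)
    records <- read_model_records(models_file)
    accepted <- structure(list(records = records, config = camp_cfg,
                               n_tried = NA_integer_,
                               n_accepted = length(records)),
                          class = "accepted_model_set")
  } else {
    if (resume)
      stop("cannot resume stage 'campaign': missing ", models_file)
    log_msg("sampling campaign: ", camp_cfg$n_samples, " draws")
    accepted <- run_sampling_campaign(preclin_expr, preclin_response,
                                      clin_expr, clin_response, camp_cfg,
                                      progress_every = 0L)
    write_model_records(accepted$records, models_file)
  }
  log_msg(accepted$n_accepted, " accepted models")
  if (accepted$n_accepted == 0L)
    stop("campaign accepted no models; relax thresholds or add draws")

  # ---- aggregation --------------------------------------------------------
  avg <- average_patient_predictions(accepted, clin_response)
  write_tsv(data.frame(sample_id = names(avg$mean_prediction),
                       mean_prediction = unname(avg$mean_prediction),
                       response = clin_response$response),
            "patient_predictions.tsv")
  min_models <- config$aggregate$min_models
  if (is.null(min_models)) min_models <- 2L
  if (identical(min_models, "auto")) {
    # "most frequently occurring" slice: counts above the upper 97.5% tail of
    # a Poisson null with the observed mean selection density
    dens <- accepted$n_accepted * camp_cfg$n_genes_per_model /
      ncol(preclin_expr)
    min_models <- stats::qpois(0.975, dens) + 1L
    log_msg("auto min_models = ", min_models)
  }
  freq <- gene_frequency_selection(accepted, min_models = min_models)
  write_tsv(freq, "gene_frequency.tsv")
  log_msg(nrow(freq), " candidate genes (>=2 models); mean-prediction r = ",
          signif(avg$r, 3))
  tissue_enr <- NULL
  if (!is.null(preclin_response$tissue)) {
    labels <- stats::setNames(preclin_response$tissue,
                              preclin_response$sample_id)
    tissue_enr <- incidence_enrichment(accepted, labels)
    write_tsv(tissue_enr, "tissue_enrichment.tsv")
  }

  # ---- enrichment + clustering -------------------------------------------
  q_max <- if (is.null(config$enrichment$q_max)) 0.05
           else config$enrichment$q_max
  enr <- overlap_enrichment(freq$gene, gene_sets, q_max = q_max)
  if (nrow(enr) == 0L)
    stop("no enriched pathway at q <= ", q_max)
  write_tsv(enr[, setdiff(colnames(enr), "overlap_genes")], "enrichment.tsv")
  log_msg(nrow(enr), " enriched pathways (q <= ", q_max, ")")
  M <- membership_matrix(enr)
  clust <- if (nrow(M) >= 2L && ncol(M) >= 2L)
    cluster_pathway_gene(M) else NULL
  ord <- if (is.null(clust)) M else M[clust$row_order, clust$col_order,
                                      drop = FALSE]
  utils::write.table(data.frame(pathway = rownames(ord), ord,
                                check.names = FALSE),
                     path("membership.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # ---- fitness ------------------------------------------------------------
  fit_cfg <- config$fitness
  mode <- if (is.null(fit_cfg$mode)) "ttest_quantile" else fit_cfg$mode
  tail_fraction <- if (is.null(fit_cfg$tail_fraction)) 0.20
                   else fit_cfg$tail_fraction
  min_genes <- if (is.null(fit_cfg$min_genes)) 5L else fit_cfg$min_genes
  p_max <- if (is.null(fit_cfg$p_max)) 0.2 else fit_cfg$p_max
  stats_df <- gene_response_statistic(clin_expr[, freq$gene, drop = FALSE],
                                      clin_response, mode = mode,
                                      tail_fraction = tail_fraction)
  pathways <- stats::setNames(enr$overlap_genes, enr$pathway)
  delta <- delta_fitness(stats_df, pathways, p_max = p_max,
                         min_genes = min_genes)
  write_tsv(delta$fitness, "fitness.tsv")
  write_tsv(delta$gene_table, "delta_genes.tsv")
  log_msg(sum(delta$fitness$H != 0), " pathways with nonzero H")

  # ---- panel + evaluation -------------------------------------------------
  panel_pct <- if (is.null(config$panel$pct)) 0.40 else config$panel$pct
  panel_pmax <- if (is.null(config$panel$p_max)) 0.2 else config$panel$p_max
  panel <- select_biomarkers(delta, p_max = panel_pmax, pct = panel_pct)
  write_tsv(panel$table, "panel.tsv")
  log_msg(length(panel$genes), " panel genes")
  evaluation <- split <- pooled <- NULL
  if (length(panel$genes) >= 2L) {
    ev_cfg <- config$evaluate
    n_trees <- if (is.null(ev_cfg$n_trees)) 500L else ev_cfg$n_trees
    n_seeds <- if (is.null(ev_cfg$n_seeds)) 50L else ev_cfg$n_seeds
    ev_seed <- if (is.null(ev_cfg$seed)) camp_cfg$seed else ev_cfg$seed
    panel_expr <- clin_expr[, panel$genes, drop = FALSE]
    split <- optimize_class_split(panel_expr, clin_response,
                                  n_seeds = max(5L, n_seeds %/% 2L),
                                  n_trees = n_trees, seed = ev_seed)
    evaluation <- rf_evaluate(panel_expr, split$classes, n_trees = n_trees,
                              n_seeds = n_seeds, seed = ev_seed)
    write_tsv(data.frame(
      split_k = split$split_k,
      responder_error = evaluation$responder_error,
      responder_error_sd = evaluation$responder_error_sd,
      nonresponder_error = evaluation$nonresponder_error,
      nonresponder_error_sd = evaluation$nonresponder_error_sd,
      auc_mean = evaluation$auc_mean, auc_sd = evaluation$auc_sd,
      auc_vs_half_p = evaluation$auc_vs_half_p), "rf_evaluation.tsv")
    log_msg(sprintf("RF split k = %d; responder error %.1f%%, AUC %.2f",
                    split$split_k, evaluation$responder_error,
                    evaluation$auc_mean))
    if (length(panel$positive_pool) >= 2L &&
        length(panel$negative_pool) >= 2L) {
      pooled <- pooled_tstat_classifier(clin_expr, panel$positive_pool,
                                        panel$negative_pool, clin_response)
      write_tsv(data.frame(sample_id = names(pooled$t),
                           pooled_t = unname(pooled$t),
                           response = clin_response$response),
                "pooled_t.tsv")
      log_msg(sprintf("pooled-t classifier r = %.3f", pooled$r))
    }
  }

  # ---- network ------------------------------------------------------------
  net_pct <- if (is.null(config$network$pct)) 0.20 else config$network$pct
  network <- tryCatch(
    build_network(delta$fitness, pathways, gene_attrs = delta$gene_table,
                  pct = net_pct),
    error = function(e) {
      log_msg("network stage skipped: ", conditionMessage(e))
      NULL
    })
  if (!is.null(network)) {
    export_network(network, path("network.sif"), format = "sif")
    neg_pw <- delta$fitness$pathway[delta$fitness$H < 0]
    neg_genes <- unique(unlist(pathways[neg_pw]))
    if (nrow(network$nodes) >= 2L)
      export_correlation_matrix(
        clin_expr[, network$nodes$gene, drop = FALSE],
        path("correlation_matrix.tsv"),
        negative_genes = intersect(network$nodes$gene, neg_genes))
  }

  # ---- provenance ---------------------------------------------------------
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL   # hash the analysis, not its location
  prov <- list(
    config_hash = sum(utf8ToInt(paste(deparse(cfg_for_hash),
                                      collapse = ""))) %% 2147483647,
    seed = camp_cfg$seed,
    package_version = as.character(utils::packageVersion("pathmarker")),
    n_accepted_models = accepted$n_accepted,
    n_candidate_genes = nrow(freq),
    n_enriched_pathways = nrow(enr),
    n_panel_genes = length(panel$genes))
  jsonlite::write_json(prov, path("provenance.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(data = data, accepted = accepted, average = avg,
                 gene_frequency = freq, tissue_enrichment = tissue_enr,
                 enrichment = enr, membership = M, clustering = clust,
                 response_stats = stats_df, delta = delta, panel = panel,
                 split = split, evaluation = evaluation, pooled = pooled,
                 network = network, out_dir = out_dir))
}
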