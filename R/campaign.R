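#' Configuration of a random-sampling ridge campaign
#'
#' Defaults reproduce the screening regime of the method: random picks of 30
#' tumor cells and 300 genes, dual-filter thresholds ln(pval_IC50) < -11 and
#' ln(pval_clinical) < -6 with ppv/npv at least 0.45, and the 80% range rule.
#'
#' @param n_samples number of random picks to evaluate.
#' @param n_cells_per_model,n_genes_per_model subset sizes per model.
#' @param ln_pval_ic50_max,ln_pval_clinical_max acceptance thresholds on the
#'   natural-log p-values (accept strictly below).
#' @param ppv_min,npv_min minimum positive/negative predictive values.
#' @param range_fraction required ratio of predicted to observed range.
#' @param seed RNG seed for the sampling stream.
#' @return list of class `campaign_config`.
#' @export
campaign_config <- function(n_samples, n_cells_per_model = 30L,
                            n_genes_per_model = 300L,
                            ln_pval_ic50_max = -11, ln_pval_clinical_max = -6,
                            ppv_min = 0.45, npv_min = 0.45,
                            range_fraction = 0.8, seed = 1L) {
  stopifnot(n_samples >= 0, n_cells_per_model >= 3, n_genes_per_model >= 1,
            range_fraction >= 0, range_fraction <= 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_cells_per_model = as.integer(n_cells_per_model),
                 n_genes_per_model = as.integer(n_genes_per_model),
                 ln_pval_ic50_max = ln_pval_ic50_max,
                 ln_pval_clinical_max = ln_pval_clinical_max,
                 ppv_min = ppv_min, npv_min = npv_min,
                 range_fraction = range_fraction, seed = as.integer(seed)),
            class = "campaign_config")
}

#' Dual-filter statistics of one training model
#'
#' Computes the full set of filter statistics for a sampled ridge model:
#' (i) Pearson r and ln p of the in-sample predicted IC50 against the
#' per-cell mean expression of the model's genes (`pval_IC50`); (ii) Pearson
#' r and ln p of the predicted patient chemosensitivity scores against months
#' to progression (`pval_clinical`); (iii) range flags requiring the spread of
#' the predictions to reach `range_fraction` of the observed spread (predicted
#' IC50 vs observed IC50 over the model's cells; patient scores, which live on
#' the IC50 scale, vs the in-sample predicted IC50); (iv) ppv/npv of the
#' mean-threshold dichotomization of the patient scores.
#'
#' @param record [sampling_model_record()].
#' @param preclin_expr,clin_expr samples x genes matrices over the common
#'   gene universe.
#' @param preclin_response,clin_response response tables (IC50; months to
#'   progression).
#' @param range_fraction the range-rule fraction (default 0.8).
#' @return list of filter statistics; `defined` is FALSE when any statistic is
#'   degenerate (such a model always fails the filter).
#' @export
evaluate_training_model <- function(record, preclin_expr, preclin_response,
                                    clin_expr, clin_response,
                                    range_fraction = 0.8) {
  obs_ic50 <- preclin_response$response[
    match(record$cell_subset, preclin_response$sample_id)]
  if (anyNA(obs_ic50)) stop("model cell missing from preclinical response")
  mean_expr <- rowMeans(preclin_expr[record$cell_subset, record$gene_subset,
                                     drop = FALSE])
  pfs <- clin_response$response
  cv <- classification_values(record$pred_clinical, pfs,
                              observed_direction = "survival")
  ic50_cor <- tryCatch(pearson_with_pvalue(record$pred_ic50, mean_expr),
                       error = function(e) NULL)
  clin_cor <- tryCatch(pearson_with_pvalue(record$pred_clinical, pfs),
                       error = function(e) NULL)
  defined <- !is.null(ic50_cor) && !is.null(clin_cor) && isTRUE(cv$defined)
  pred_range <- diff(range(record$pred_ic50))
  list(r_ic50 = if (!is.null(ic50_cor)) ic50_cor$r else NA_real_,
       ln_pval_ic50 = if (!is.null(ic50_cor)) ic50_cor$ln_p else NA_real_,
       r_clinical = if (!is.null(clin_cor)) clin_cor$r else NA_real_,
       ln_pval_clinical = if (!is.null(clin_cor)) clin_cor$ln_p else NA_real_,
       ppv_clinical = cv$ppv, npv_clinical = cv$npv,
       range_ok_ic50 = pred_range >= range_fraction * diff(range(obs_ic50)),
       range_ok_clinical =
         diff(range(record$pred_clinical)) >= range_fraction * pred_range,
       defined = defined)
}

#' Apply the dual filter to one model's statistics
#'
#' Accepts a model only if the preclinical and clinical correlation p-values
#' both beat their thresholds, ppv and npv reach their minima, and both range
#' flags hold. Undefined statistics reject.
#'
#' @param stats list from [evaluate_training_model()].
#' @param config [campaign_config()].
#' @return logical.
#' @export
dual_filter <- function(stats, config) {
  if (!isTRUE(stats$defined)) return(FALSE)
  isTRUE(stats$ln_pval_ic50 < config$ln_pval_ic50_max) &&
    isTRUE(stats$ln_pval_clinical < config$ln_pval_clinical_max) &&
    isTRUE(stats$ppv_clinical >= config$ppv_min) &&
    isTRUE(stats$npv_clinical >= config$npv_min) &&
    isTRUE(stats$range_ok_ic50) && isTRUE(stats$range_ok_clinical)
}

#' Run the random-sampling ridge campaign
#'
#' For each draw: sample a cell subset and gene subset uniformly without
#' replacement, select the ridge penalty from the training subset alone, fit
#' the ridge model, score all patients, evaluate the filter statistics and
#' keep the model if it passes the dual filter. The draw stream is seeded and
#' fully reproducible.
#'
#' @param preclin_expr,clin_expr samples x genes matrices sharing a gene
#'   universe (see [intersect_expression()]).
#' @param preclin_response IC50 response table over the preclinical samples.
#' @param clin_response months-to-progression response table over patients.
#' @param config [campaign_config()].
#' @param checkpoint optional path; campaign state is written there every
#'   `progress_every` draws and a subsequent call resumes from it.
#' @param progress_every log counters every this many draws (0 = quiet).
#' @return object of class `accepted_model_set`: list with `records`,
#'   `config`, `n_tried`, `n_accepted`.
#' @export
run_sampling_campaign <- function(preclin_expr, preclin_response,
                                  clin_expr, clin_response, config,
                                  checkpoint = NULL, progress_every = 10000L) {
  preclin_expr <- as_expression_matrix(preclin_expr)
  clin_expr <- as_expression_matrix(clin_expr)
  if (!setequal(colnames(preclin_expr), colnames(clin_expr)))
    stop("gene universes differ; run intersect_expression() first")
  clin_expr <- clin_expr[, colnames(preclin_expr), drop = FALSE]
  if (config$n_cells_per_model > nrow(preclin_expr))
    stop("cell subset size exceeds available cells")
  if (config$n_genes_per_model > ncol(preclin_expr))
    stop("gene subset size exceeds available genes")
  if (!identical(preclin_response$sample_id, rownames(preclin_expr)))
    preclin_response <- preclin_response[
      match(rownames(preclin_expr), preclin_response$sample_id), ]
  if (anyNA(preclin_response$response))
    stop("preclinical response missing for some cells")
  if (!identical(clin_response$sample_id, rownames(clin_expr)))
    clin_response <- clin_response[
      match(rownames(clin_expr), clin_response$sample_id), ]
  if (anyNA(clin_response$response))
    stop("clinical response missing for some patients")

  cells <- rownames(preclin_expr)
  genes <- colnames(preclin_expr)
  ic50 <- preclin_response$response

  start <- 0L
  records <- list()
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    state <- jsonlite::fromJSON(checkpoint, simplifyVector = TRUE)
    start <- state$draws_done
    assign(".Random.seed", as.integer(state$rng_state), envir = globalenv())
    if (file.exists(paste0(checkpoint, ".records")))
      records <- read_model_records(paste0(checkpoint, ".records"))
    message("resuming campaign at draw ", start + 1L,
            " (", length(records), " accepted so far)")
  } else {
    set.seed(config$seed)
  }

  for (i in seq_len(config$n_samples)) {
    if (i <= start) next
    cell_idx <- sample.int(length(cells), config$n_cells_per_model)
    gene_idx <- sample.int(length(genes), config$n_genes_per_model)
    X <- preclin_expr[cell_idx, gene_idx, drop = FALSE]
    y <- ic50[cell_idx]
    lambda <- select_ridge_lambda(X, y)
    fit <- fit_linear_ridge(X, y, lambda)
    pred_clin <- drop(fit$intercept +
                        clin_expr[, gene_idx, drop = FALSE] %*%
                        fit$coefficients)
    rec <- sampling_model_record(cells[cell_idx], genes[gene_idx], lambda,
                                 fit$intercept, fit$coefficients, fit$fitted,
                                 pred_clin, stats = NULL)
    st <- evaluate_training_model(rec, preclin_expr, preclin_response,
                                  clin_expr, clin_response,
                                  range_fraction = config$range_fraction)
    rec$stats <- st
    if (dual_filter(st, config)) records[[length(records) + 1L]] <- rec
    if (progress_every > 0L && i %% progress_every == 0L)
      message("draw ", i, "/", config$n_samples, ": ",
              length(records), " accepted")
    if (!is.null(checkpoint) && progress_every > 0L &&
        i %% progress_every == 0L) {
      write_model_records(records, paste0(checkpoint, ".records"))
      jsonlite::write_json(list(draws_done = i,
                                rng_state = get(".Random.seed",
                                                envir = globalenv())),
                           checkpoint, auto_unbox = TRUE)
    }
  }
  structure(list(records = records, config = config,
                 n_tried = config$n_samples,
                 n_accepted = length(records)),
            class = "accepted_model_set")
}

#' @export
print.accepted_model_set <- function(x, ...) {
  cat("Sampling campaign:", x$n_accepted, "of", x$n_tried,
      "models accepted\n")
  cat("  per model:", x$config$n_cells_per_model, "cells x",
      x$config$n_genes_per_model, "genes\n")
  cat(sprintf("  thresholds: ln p_IC50 < %g, ln p_clinical < %g, ppv >= %g, npv >= %g\n",
              x$config$ln_pval_ic50_max, x$config$ln_pval_clinical_max,
              x$config$ppv_min, x$config$npv_min))
  if (x$n_accepted > 0) {
    r <- vapply(x$records, function(r) r$stats$r_clinical, 1)
    cat(sprintf("  accepted-model clinical r: mean %.3f (range %.3f to %.3f)\n",
                mean(r), min(r), max(r)))
  }
  invisible(x)
}
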