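#' Average patient predictions over accepted models
#'
#' Element-wise mean of the per-model patient chemosensitivity scores, with
#' the Pearson correlation of the averaged prediction against months to
#' progression.
#'
#' @param accepted `accepted_model_set` from [run_sampling_campaign()].
#' @param clin_response clinical response table (patients in the order the
#'   campaign scored them).
#' @return list with `mean_prediction` (named by patient), `r`, `ln_p`.
#' @export
average_patient_predictions <- function(accepted, clin_response) {
  if (length(accepted$records) == 0L) stop("no accepted models")
  preds <- vapply(accepted$records, function(r) r$pred_clinical,
                  numeric(nrow(clin_response)))
  m <- rowMeans(as.matrix(preds))
  names(m) <- clin_response$sample_id
  ct <- pearson_with_pvalue(m, clin_response$response)
  list(mean_prediction = m, r = ct$r, ln_p = ct$ln_p)
}

#' Candidate biomarker genes by frequency across accepted models
#'
#' @param accepted `accepted_model_set`.
#' @param min_models minimum number of accepted models a gene must appear in
#'   (default 2).
#' @return data.frame with `gene` and `count`, sorted by count descending
#'   then gene name, restricted to `count >= min_models`.
#' @export
gene_frequency_selection <- function(accepted, min_models = 2L) {
  if (length(accepted$records) == 0L) stop("no accepted models")
  counts <- table(unlist(lapply(accepted$records, `[[`, "gene_subset")))
  out <- data.frame(gene = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[out$count >= min_models, , drop = FALSE]
  out <- out[order(-out$count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fisher enrichment of accepted models for cell or tissue labels
#'
#' Builds, for each label, the 2x2 incidence table over (cell, model)
#' selection slots: a = selections of label cells, b = selections of other
#' cells, c = unselected label slots, d = unselected other slots; tests
#' enrichment with a one-sided Fisher exact test.
#'
#' @param accepted `accepted_model_set`.
#' @param labels named character vector: label per background cell (cell ids
#'   as names). Use the cell ids themselves to test per-cell enrichment.
#' @param background character vector of all screened cell ids.
#' @return data.frame with per-label counts `a`,`b`,`c`,`d`, odds ratio and
#'   one-sided p, plus attribute `n_cells_used` = cells appearing in at least
#'   one accepted model.
#' @export
incidence_enrichment <- function(accepted, labels, background = names(labels)) {
  if (length(accepted$records) == 0L) stop("no accepted models")
  sel <- unlist(lapply(accepted$records, `[[`, "cell_subset"))
  unknown <- setdiff(unique(sel), background)
  if (length(unknown))
    stop("unknown cell in accepted model: ", paste(unknown, collapse = ", "))
  labels <- labels[background]
  n_models <- length(accepted$records)
  total_slots <- n_models * length(background)
  sel_label <- labels[sel]
  rows <- lapply(sort(unique(labels)), function(L) {
    a <- sum(sel_label == L)
    b <- length(sel) - a
    label_slots <- n_models * sum(labels == L)
    c_ <- label_slots - a
    d <- total_slots - label_slots - b
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                             alternative = "greater")
    data.frame(label = L, a = a, b = b, c = c_, d = d,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_cells_used") <- length(unique(sel))
  out
}

#' Percentile-tail differential expression by Welch t-test
#'
#' The traditional comparison: per gene, a two-sample Welch t-test between
#' samples in the upper and lower `tail_fraction` of the response (e.g. the
#' most sensitive vs most resistant cells, or the best vs worst responding
#' patients). Significance is unadjusted by default, with an optional BH
#' correction.
#'
#' @param expr samples x genes matrix.
#' @param response response table over the same samples.
#' @param tail_fraction fraction of samples in each tail (default 0.30).
#' @param alpha significance threshold (default 0.05).
#' @param adjust if TRUE, apply Benjamini-Hochberg before thresholding.
#' @return list with `stats` (data.frame gene, t, df, p; t is upper-tail
#'   minus lower-tail group) and `significant` (gene vector).
#' @export
percentile_ttest_de <- function(expr, response, tail_fraction = 0.30,
                                alpha = 0.05, adjust = FALSE) {
  expr <- as_expression_matrix(expr)
  resp <- response$response[match(rownames(expr), response$sample_id)]
  if (anyNA(resp)) stop("response missing for some samples")
  n <- length(resp)
  k <- floor(tail_fraction * n)
  if (2L * k > n) stop("tail groups overlap: tail_fraction too large")
  if (k < 3L) stop("need at least 3 samples per tail")
  ord <- order(resp)
  lower <- ord[seq_len(k)]
  upper <- ord[seq.int(n - k + 1L, n)]
  wt <- welch_t_columns(expr[upper, , drop = FALSE],
                        expr[lower, , drop = FALSE])
  p_sel <- if (adjust) stats::p.adjust(wt$p, method = "BH") else wt$p
  stats_df <- data.frame(gene = colnames(expr), t = unname(wt$t),
                         df = unname(wt$df), p = unname(wt$p),
                         stringsAsFactors = FALSE)
  if (adjust) stats_df$q <- unname(p_sel)
  list(stats = stats_df, significant = colnames(expr)[p_sel < alpha],
       upper = rownames(expr)[upper], lower = rownames(expr)[lower])
}
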