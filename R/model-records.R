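RECORD_SCHEMA_VERSION <- "pathmarker-model-1"

#' Construct one sampled ridge training-model record
#'
#' A record captures everything about a single random cell/gene pick: the
#' subsets, the fitted ridge model, its in-sample IC50 predictions, its
#' patient predictions, and the dual-filter statistics.
#'
#' @param cell_subset,gene_subset character vectors of sampled ids.
#' @param lambda nonnegative ridge parameter.
#' @param intercept,coefficients fitted model (coefficients aligned to
#'   `gene_subset`).
#' @param pred_ic50 in-sample predictions over `cell_subset`.
#' @param pred_clinical predicted chemosensitivity scores over all patients.
#' @param stats list of filter statistics (see [evaluate_training_model()]).
#' @return list of class `sampling_model_record`.
#' @export
sampling_model_record <- function(cell_subset, gene_subset, lambda, intercept,
                                  coefficients, pred_ic50, pred_clinical,
                                  stats) {
  if (length(coefficients) != length(gene_subset))
    stop("coefficient length must equal gene subset length")
  if (length(pred_ic50) != length(cell_subset))
    stop("pred_ic50 must align with cell subset")
  if (!is.null(names(coefficients)) &&
      !identical(names(coefficients), as.character(gene_subset)))
    stop("coefficient names do not match gene subset")
  structure(list(cell_subset = as.character(cell_subset),
                 gene_subset = as.character(gene_subset),
                 lambda = as.numeric(lambda),
                 intercept = as.numeric(intercept),
                 coefficients = unname(as.numeric(coefficients)),
                 pred_ic50 = unname(as.numeric(pred_ic50)),
                 pred_clinical = unname(as.numeric(pred_clinical)),
                 stats = stats),
            class = "sampling_model_record")
}

#' Write sampled model records as line-delimited JSON
#'
#' One model per line with an explicit schema-version tag, so campaign output
#' is append-only and stream-readable.
#'
#' @param records list of [sampling_model_record()] objects.
#' @param path output file.
#' @export
write_model_records <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (rec in records) {
    payload <- unclass(rec)
    payload$schema <- RECORD_SCHEMA_VERSION
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(path)
}

#' Read model records written by [write_model_records()]
#' @param path line-delimited JSON file.
#' @return list of `sampling_model_record` objects.
#' @export
read_model_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    payload <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                        error = function(e)
                          stop("corrupt model record at line ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    if (!identical(payload$schema, RECORD_SCHEMA_VERSION))
      stop("schema version mismatch at line ", i, ": expected '",
           RECORD_SCHEMA_VERSION, "', got '", payload$schema, "'")
    stats <- payload$stats
    # scalars arrive as length-1 vectors; NULL stays NULL for undefined stats
    out[[i]] <- sampling_model_record(payload$cell_subset, payload$gene_subset,
                                      payload$lambda, payload$intercept,
                                      payload$coefficients, payload$pred_ic50,
                                      payload$pred_clinical, stats)
  }
  out
}
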