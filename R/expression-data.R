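#' Validate a samples x genes expression matrix
#'
#' The pipeline represents baseline expression as a plain numeric matrix with
#' samples (cell lines or patients) in rows and genes in columns, identified
#' by unique dimnames. Values are log-scale expression units and are used
#' unscaled throughout.
#'
#' @param values numeric matrix, samples x genes.
#' @param sample_ids,gene_ids optional character vectors overriding dimnames.
#' @return the validated matrix with dimnames set.
#' @export
as_expression_matrix <- function(values, sample_ids = rownames(values),
                                 gene_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (is.null(sample_ids) || is.null(gene_ids))
    stop("expression matrix needs sample and gene identifiers")
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(values) || length(gene_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample id: ", paste(dup, collapse = ", "))
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene id: ", paste(dup, collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite (no NA/NaN/Inf)")
  dimnames(values) <- list(sample_ids, gene_ids)
  values
}

#' Read an expression matrix from a tab-delimited file
#'
#' @param path file with a header row; first column holds row identifiers.
#' @param orientation `"rows-are-genes"` (the usual repository export) or
#'   `"rows-are-samples"`. The returned matrix is always samples x genes.
#' @return numeric matrix, samples x genes.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("rows-are-genes",
                                                   "rows-are-samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (nrow(tab) == 0L || ncol(tab) < 2L)
    stop("expression file has no data body: ", path)
  row_ids <- tab[[1L]]
  col_ids <- colnames(tab)[-1L]   # before subsetting: `[.data.frame` dedups
  body <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at data row %d, column '%s'",
                 bad[["row"]], col_ids[bad[["col"]]]))
  }
  dimnames(num) <- list(row_ids, col_ids)
  if (orientation == "rows-are-genes") num <- t(num)
  tryCatch(as_expression_matrix(num), error = function(e) {
    stop(conditionMessage(e), call. = FALSE)
  })
}

#' Write an expression matrix to a tab-delimited file
#'
#' @param expr samples x genes matrix (see [as_expression_matrix()]).
#' @param path output path.
#' @param orientation file orientation, as in [read_expression_matrix()].
#' @param id_column header label of the identifier column.
#' @export
write_expression_matrix <- function(expr, path,
                                    orientation = c("rows-are-genes",
                                                    "rows-are-samples"),
                                    id_column = "id") {
  orientation <- match.arg(orientation)
  expr <- as_expression_matrix(expr)
  out <- if (orientation == "rows-are-genes") t(expr) else expr
  tab <- data.frame(rownames(out), out, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab)[1L] <- id_column
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a per-sample response table
#'
#' Holds one scalar phenotype per sample: IC50 in the preclinical role,
#' months to progression in the clinical role, plus an optional tissue label.
#'
#' @param sample_ids character vector, unique.
#' @param response finite numeric vector, same length.
#' @param tissue optional character vector of tissue labels.
#' @return data.frame with columns `sample_id`, `response` and, when given,
#'   `tissue`.
#' @export
response_table <- function(sample_ids, response, tissue = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  response <- as.numeric(response)
  if (length(response) != length(sample_ids))
    stop("response length does not match sample ids")
  if (!all(is.finite(response))) {
    bad <- sample_ids[!is.finite(response)]
    stop("non-finite response for sample: ", paste(bad, collapse = ", "))
  }
  out <- data.frame(sample_id = sample_ids, response = response,
                    stringsAsFactors = FALSE)
  if (!is.null(tissue)) {
    if (length(tissue) != length(sample_ids))
      stop("tissue length does not match sample ids")
    out$tissue <- as.character(tissue)
  }
  out
}

#' Read a response table from a tab-delimited file
#'
#' Expects columns `sample_id` and `response`, optionally `tissue`; any other
#' column is ignored with a warning. File order is preserved.
#'
#' @param path tab-delimited file with a header row.
#' @return data.frame as from [response_table()].
#' @export
read_response_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (nrow(tab) == 0L) stop("no samples in response table: ", path)
  need <- c("sample_id", "response")
  if (!all(need %in% colnames(tab)))
    stop("response table must have columns 'sample_id' and 'response'")
  extra <- setdiff(colnames(tab), c(need, "tissue"))
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  resp <- suppressWarnings(as.numeric(tab$response))
  if (anyNA(resp))
    stop("missing or non-numeric response for sample: ",
         paste(tab$sample_id[is.na(resp)], collapse = ", "))
  response_table(tab$sample_id, resp,
                 tissue = if ("tissue" %in% colnames(tab)) tab$tissue)
}

#' Write a response table
#' @param tab data.frame from [response_table()].
#' @param path output path.
#' @export
write_response_table <- function(tab, path) {
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict two expression matrices to their common gene universe
#'
#' The preclinical and clinical matrices are reduced to the intersection of
#' their gene sets, in identical gene order, before any modeling.
#'
#' @param preclinical,clinical samples x genes matrices.
#' @return list with elements `preclinical` and `clinical`.
#' @export
intersect_expression <- function(preclinical, clinical) {
  preclinical <- as_expression_matrix(preclinical)
  clinical <- as_expression_matrix(clinical)
  common <- intersect(colnames(preclinical), colnames(clinical))
  if (length(common) == 0L) stop("empty gene intersection")
  list(preclinical = preclinical[, common, drop = FALSE],
       clinical = clinical[, common, drop = FALSE])
}
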