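#' Select the biomarker panel from delta(fitness) contributions
#'
#' Keeps genes with a modest statistical match to patient response
#' (p < `p_max`) whose delta(fitness) falls in the upper or lower `pct`
#' percentile of the whole set of delta scores. Selected genes are routed
#' into a positive or negative pool by the sign of the summed fitness of the
#' pathways contributing their delta.
#'
#' @param delta result of [delta_fitness()] (its `gene_table`), or a
#'   data.frame with columns `gene`, `delta`, `sum_H`, `p`.
#' @param p_max response-significance cutoff (default 0.2).
#' @param pct percentile tail of the delta scores (default 0.40).
#' @return list of class `biomarker_panel` with `genes`, `table` (selection
#'   metadata), `positive_pool`, `negative_pool`.
#' @export
select_biomarkers <- function(delta, p_max = 0.2, pct = 0.40) {
  tab <- if (is.data.frame(delta)) delta else delta$gene_table
  if (is.null(tab) || nrow(tab) == 0L) stop("empty delta(fitness) table")
  tab <- tab[tab$p < p_max, , drop = FALSE]
  if (nrow(tab) == 0L) {
    message("no genes pass the response-significance cutoff: empty panel")
    return(structure(list(genes = character(), table = tab,
                          positive_pool = character(),
                          negative_pool = character()),
                     class = "biomarker_panel"))
  }
  hi <- stats::quantile(tab$delta, 1 - pct, names = FALSE)
  lo <- stats::quantile(tab$delta, pct, names = FALSE)
  keep <- tab$delta >= hi | tab$delta <= lo
  tab <- tab[keep, , drop = FALSE]
  tab$pool <- ifelse(tab$sum_H > 0, "positive", "negative")
  structure(list(genes = tab$gene, table = tab,
                 positive_pool = tab$gene[tab$pool == "positive"],
                 negative_pool = tab$gene[tab$pool == "negative"]),
            class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat("Biomarker panel:", length(x$genes), "genes (",
      length(x$positive_pool), "positive-fitness /",
      length(x$negative_pool), "negative-fitness )\n")
  invisible(x)
}

#' Two-way clustering of panel gene expressions with a clade response test
#'
#' Euclidean-distance, Ward-linkage clustering of genes and patients, plus a
#' Welch t-test of months to progression between designated patient clades.
#'
#' @param expr patients x genes matrix restricted to the panel.
#' @param response optional clinical response table; enables the clade test.
#' @param n_clades number of patient clades to cut (default 2).
#' @param clade_groups list of two vectors of clade labels to compare
#'   (default: clade 1 vs the rest).
#' @return list with `gene_tree`, `patient_tree`, orders, `clades` (label per
#'   patient), and `clade_test` (t, df, p; NULL when skipped).
#' @export
cluster_expression <- function(expr, response = NULL, n_clades = 2L,
                               clade_groups = NULL) {
  expr <- as_expression_matrix(expr)
  if (nrow(expr) < 2L || ncol(expr) < 2L)
    stop("need at least 2 genes and 2 patients")
  gene_tree <- stats::hclust(stats::dist(t(expr)), method = "ward.D2")
  patient_tree <- stats::hclust(stats::dist(expr), method = "ward.D2")
  clades <- stats::cutree(patient_tree, k = min(n_clades, nrow(expr)))
  clade_test <- NULL
  if (!is.null(response)) {
    resp <- response$response[match(rownames(expr), response$sample_id)]
    if (is.null(clade_groups))
      clade_groups <- list(1L, setdiff(unique(clades), 1L))
    g1 <- resp[clades %in% clade_groups[[1L]]]
    g2 <- resp[clades %in% clade_groups[[2L]]]
    if (length(g1) < 2L || length(g2) < 2L) {
      warning("clade group with fewer than 2 patients: response test skipped")
    } else {
      clade_test <- welch_t(g1, g2)
    }
  }
  list(gene_tree = gene_tree, patient_tree = patient_tree,
       gene_order = gene_tree$order, patient_order = patient_tree$order,
       clades = clades, clade_test = clade_test)
}

# Stratified index partition into sample/validation/test fractions; every
# class keeps at least one sample in the training partition.
.stratified_partition <- function(classes, fractions) {
  idx <- seq_along(classes)
  part <- character(length(classes))
  for (cl in unique(classes)) {
    members <- sample(idx[classes == cl])
    n <- length(members)
    n_train <- max(round(fractions[1L] * n), 1L)
    n_val <- round(fractions[2L] * n)
    n_val <- min(n_val, n - n_train)
    part[members] <- rep(c("sample", "validation", "test"),
                         c(n_train, n_val, n - n_train - n_val))
  }
  part
}

#' Random-forest evaluation of a biomarker panel
#'
#' For each seed, patients are split into sample/validation/test partitions
#' (stratified by class), a forest is trained on the sample partition,
#' per-class errors are read from the out-of-bag votes, and the AUC is
#' computed from class-probability votes on the test partition. Results are
#' averaged over seeds and the AUC list is tested against the no-information
#' value 0.5.
#'
#' @param expr patients x genes matrix restricted to the panel.
#' @param classes factor or vector with two levels; the *first* level is
#'   treated as the responder class.
#' @param n_trees trees per forest (default 500).
#' @param n_seeds number of forests with different seeds (default 50).
#' @param partition sample/validation/test fractions (default 0.70/0.15/0.15).
#' @param seed base seed of the evaluation stream.
#' @param holdout if TRUE, per-class errors come from the test partition
#'   instead of the out-of-bag votes.
#' @return list of class `rf_evaluation`: per-class error mean/sd (percent),
#'   `auc_values`, `auc_mean`, `auc_sd`, `auc_vs_half_p`.
#' @export
rf_evaluate <- function(expr, classes, n_trees = 500L, n_seeds = 50L,
                        partition = c(0.70, 0.15, 0.15), seed = 1L,
                        holdout = FALSE) {
  expr <- as.matrix(expr)
  classes <- factor(classes)
  if (nlevels(classes) != 2L) stop("need exactly two classes")
  if (min(table(classes)) < 3L) stop("each class needs at least 3 members")
  if (all(apply(expr, 2L, stats::sd) == 0))
    stop("all features constant: nothing to learn from")
  responder <- levels(classes)[1L]
  err <- matrix(NA_real_, n_seeds, 2L,
                dimnames = list(NULL, levels(classes)))
  auc <- rep(NA_real_, n_seeds)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(seeds[s])
    part <- .stratified_partition(classes, partition)
    use_test <- sum(partition[2:3]) > 0 && any(part == "test") &&
      length(unique(classes[part == "test"])) == 2L
    train <- part == "sample"
    rf <- randomForest::randomForest(expr[train, , drop = FALSE],
                                     classes[train], ntree = n_trees)
    if (holdout && any(!train)) {
      pred <- stats::predict(rf, expr[!train, , drop = FALSE])
      tab <- table(observed = classes[!train], predicted = pred)
      err[s, ] <- 100 * (1 - diag(tab) / pmax(rowSums(tab), 1L))
    } else {
      conf <- rf$confusion
      err[s, ] <- 100 * conf[levels(classes), "class.error"]
    }
    if (use_test) {
      prob <- stats::predict(rf, expr[part == "test", , drop = FALSE],
                             type = "prob")[, responder]
      obs <- classes[part == "test"]
      if (length(unique(prob)) > 1L || TRUE)
        auc[s] <- tryCatch(
          as.numeric(pROC::auc(pROC::roc(obs, prob, levels = levels(classes),
                                         direction = ">", quiet = TRUE))),
          error = function(e) NA_real_)
    }
  }
  auc_values <- auc[!is.na(auc)]
  # degenerate point mass (every seed identical): report 0 away from chance
  auc_test <- if (length(auc_values) >= 2L && stats::sd(auc_values) > 0)
    stats::t.test(auc_values, mu = 0.5)$p.value
  else if (length(auc_values) >= 2L && mean(auc_values) != 0.5) 0
  else NA_real_
  structure(list(responder_class = responder,
                 responder_error = mean(err[, responder]),
                 responder_error_sd = stats::sd(err[, responder]),
                 nonresponder_error = mean(err[, setdiff(levels(classes),
                                                         responder)]),
                 nonresponder_error_sd = stats::sd(err[, setdiff(levels(classes),
                                                                 responder)]),
                 errors = err, auc_values = auc_values,
                 auc_mean = mean(auc_values), auc_sd = stats::sd(auc_values),
                 auc_vs_half_p = auc_test, n_seeds = n_seeds),
            class = "rf_evaluation")
}

#' @export
print.rf_evaluation <- function(x, ...) {
  cat(sprintf("Random-forest evaluation (%d seeds)\n", x$n_seeds))
  cat(sprintf("  responder error:     %.1f +- %.1f %%\n",
              x$responder_error, x$responder_error_sd))
  cat(sprintf("  non-responder error: %.1f +- %.1f %%\n",
              x$nonresponder_error, x$nonresponder_error_sd))
  if (length(x$auc_values))
    cat(sprintf("  AUC: %.2f +- %.2f (p vs 0.5: %.3g)\n",
                x$auc_mean, x$auc_sd, x$auc_vs_half_p))
  invisible(x)
}

#' Optimize the responder/non-responder class split
#'
#' Patients are ordered by response (best first); for each candidate split
#' size k the top-k patients form the responder class and the mean of the two
#' out-of-bag class errors (averaged over seeds) is recorded. Returns the k
#' minimizing that mean.
#'
#' @param expr patients x genes matrix.
#' @param response clinical response table.
#' @param k_range candidate responder-class sizes (default: all k leaving at
#'   least 3 patients per class).
#' @param n_seeds forests per candidate (default 25).
#' @param n_trees trees per forest (default 500).
#' @param seed RNG seed.
#' @return list with `split_k`, `classes` (factor per patient, levels
#'   responder/nonresponder), `error_curve` (data.frame k, responder_error,
#'   nonresponder_error, mean_error).
#' @export
optimize_class_split <- function(expr, response, k_range = NULL,
                                 n_seeds = 25L, n_trees = 500L, seed = 1L) {
  expr <- as.matrix(expr)
  resp <- response$response[match(rownames(expr), response$sample_id)]
  if (anyNA(resp)) stop("response missing for some patients")
  n <- length(resp)
  if (is.null(k_range)) k_range <- seq.int(3L, n - 3L)
  k_range <- k_range[k_range >= 3L & k_range <= n - 3L]
  if (length(k_range) == 0L) stop("no feasible split")
  ord <- order(resp, decreasing = TRUE)
  if (all(apply(expr, 2L, stats::sd) == 0)) {
    # uninformative features: every split is equivalent
    warning("flat error curve (constant features): ",
            "falling back to smallest candidate split")
    k <- min(k_range)
    classes <- factor(ifelse(seq_len(n) %in% ord[seq_len(k)],
                             "responder", "nonresponder"),
                      levels = c("responder", "nonresponder"))
    names(classes) <- rownames(expr)
    return(list(split_k = k, classes = classes,
                error_curve = data.frame(k = k_range,
                                         responder_error = NA_real_,
                                         nonresponder_error = NA_real_,
                                         mean_error = NA_real_)))
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_seeds)
  curve <- lapply(k_range, function(k) {
    classes <- factor(ifelse(seq_len(n) %in% ord[seq_len(k)],
                             "responder", "nonresponder"),
                      levels = c("responder", "nonresponder"))
    errs <- vapply(seeds, function(s) {
      set.seed(s)
      rf <- randomForest::randomForest(expr, classes, ntree = n_trees)
      100 * rf$confusion[levels(classes), "class.error"]
    }, numeric(2L))
    data.frame(k = k, responder_error = mean(errs[1L, ]),
               nonresponder_error = mean(errs[2L, ]),
               mean_error = mean(errs))
  })
  curve <- do.call(rbind, curve)
  if (diff(range(curve$mean_error)) < 1e-9) {
    warning("flat error curve: falling back to smallest candidate split")
    best <- 1L
  } else {
    best <- which.min(curve$mean_error)
  }
  k <- curve$k[best]
  classes <- factor(ifelse(seq_len(n) %in% ord[seq_len(k)],
                           "responder", "nonresponder"),
                    levels = c("responder", "nonresponder"))
  names(classes) <- rownames(expr)
  list(split_k = k, classes = classes, error_curve = curve)
}

#' Sensitivity of forest evaluation to subsample size
#'
#' For each requested size, draws `n_rep` stratified random subsamples of the
#' patients and evaluates one forest on each; reports mean and sd of the
#' per-class errors and AUC per size. Infeasible sizes (fewer than 2 patients
#' in a class) are skipped with a warning.
#'
#' @param expr patients x genes matrix.
#' @param classes two-level factor over patients (first level = responder).
#' @param sizes integer vector of subsample sizes.
#' @param n_rep subsamples per size (default 50).
#' @param n_trees trees per forest (default 500).
#' @param seed RNG seed.
#' @return data.frame with one row per evaluated size.
#' @export
subsample_sensitivity <- function(expr, classes, sizes, n_rep = 50L,
                                  n_trees = 500L, seed = 1L) {
  expr <- as.matrix(expr)
  classes <- factor(classes)
  n <- length(classes)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(sizes) * n_rep)
  rows <- list()
  for (j in seq_along(sizes)) {
    size <- sizes[j]
    per_class <- round(size * table(classes) / n)
    if (size > n || any(per_class < 2L)) {
      warning("infeasible subsample size ", size, ": skipped")
      next
    }
    res <- matrix(NA_real_, n_rep, 3L)
    for (r in seq_len(n_rep)) {
      set.seed(seeds[(j - 1L) * n_rep + r])
      take <- unlist(lapply(levels(classes), function(cl)
        sample(which(classes == cl), per_class[[cl]])))
      ev <- rf_evaluate(expr[take, , drop = FALSE], classes[take],
                        n_trees = n_trees, n_seeds = 1L,
                        seed = seeds[(j - 1L) * n_rep + r])
      res[r, ] <- c(ev$responder_error, ev$nonresponder_error,
                    if (length(ev$auc_values)) ev$auc_mean else NA_real_)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      size = size,
      responder_error = mean(res[, 1L]), responder_error_sd = stats::sd(res[, 1L]),
      nonresponder_error = mean(res[, 2L]),
      nonresponder_error_sd = stats::sd(res[, 2L]),
      auc_mean = mean(res[, 3L], na.rm = TRUE),
      auc_sd = stats::sd(res[, 3L], na.rm = TRUE))
  }
  do.call(rbind, rows)
}

#' SVD impact values: per-gene share of total expression variance
#'
#' Full singular value decomposition of the column-centered expression
#' matrix; with K the smallest number of components whose cumulative variance
#' share reaches `variance_share`, a gene's impact is the squared-loading
#' weighted variance it carries over those K components, normalized so the
#' impacts sum to one.
#'
#' @param expr patients x genes matrix.
#' @param variance_share cumulative variance cutoff defining K (default 0.90).
#' @return named numeric vector of impacts (sums to 1).
#' @export
svd_impact <- function(expr, variance_share = 0.90) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L || ncol(expr) < 2L)
    stop("need at least 2 genes and 2 patients")
  Xc <- scale(expr, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  tot <- sum(sv$d^2)
  if (tot == 0) stop("zero-variance expression matrix")
  K <- which(cumsum(sv$d^2) / tot >= variance_share)[1L]
  impact <- drop((sv$v[, seq_len(K), drop = FALSE]^2) %*%
                   (sv$d[seq_len(K)]^2))
  impact <- impact / sum(impact)
  names(impact) <- colnames(expr)
  impact
}

#' Pooled t-statistic per-patient classifier
#'
#' For each patient, a Welch t-statistic compares the patient's pooled
#' negative-fitness gene expressions to the pooled positive-fitness gene
#' expressions (negative minus positive); genes over-expressed relative to
#' the positive pool push t up. The per-patient t values are then correlated
#' with months to progression.
#'
#' @param clin_expr patients x genes matrix.
#' @param positive_pool,negative_pool disjoint gene lists (>= 2 genes each):
#'   top contributors to positive- and negative-fitness pathways.
#' @param response clinical response table.
#' @return list with `t` (named per-patient vector, NA when a pool is
#'   degenerate for that patient), `r`, `ln_p`.
#' @export
pooled_tstat_classifier <- function(clin_expr, positive_pool, negative_pool,
                                    response) {
  clin_expr <- as_expression_matrix(clin_expr)
  if (length(intersect(positive_pool, negative_pool)))
    stop("pools overlap")
  if (length(positive_pool) < 2L || length(negative_pool) < 2L)
    stop("each pool needs at least 2 genes")
  missing <- setdiff(c(positive_pool, negative_pool), colnames(clin_expr))
  if (length(missing))
    stop("pool genes absent from expression: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  tvals <- vapply(seq_len(nrow(clin_expr)), function(i) {
    neg <- clin_expr[i, negative_pool]
    pos <- clin_expr[i, positive_pool]
    if (stats::sd(neg) == 0 || stats::sd(pos) == 0) return(NA_real_)
    welch_t(neg, pos)$t
  }, 1)
  names(tvals) <- rownames(clin_expr)
  resp <- response$response[match(rownames(clin_expr), response$sample_id)]
  ok <- !is.na(tvals)
  if (sum(ok) < 3L) stop("too few patients with defined pooled t")
  ct <- pearson_with_pvalue(tvals[ok], resp[ok])
  list(t = tvals, r = ct$r, ln_p = ct$ln_p)
}
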