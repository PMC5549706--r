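#' Overlap gene-set enrichment with BH false-discovery control
#'
#' Hypergeometric upper-tail test of the overlap between a query gene list
#' and each pathway, given the shared gene universe. Pathways overlapping the
#' query in fewer than 2 genes are excluded before testing; BH adjustment is
#' applied across the tested pathways.
#'
#' @param query character vector of genes (a subset of the universe).
#' @param collection [gene_set_collection()].
#' @param q_max FDR threshold for reporting (default 0.05); use `Inf` to
#'   return all tested pathways.
#' @param min_overlap minimum overlap to test (default 2).
#' @return data.frame with `pathway`, `k_overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `q` and list-column `overlap_genes`, sorted by q
#'   then p.
#' @export
overlap_enrichment <- function(query, collection, q_max = 0.05,
                               min_overlap = 2L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  if (length(query) == 0L) stop("empty query gene list")
  outside <- setdiff(query, collection$universe)
  if (length(outside))
    stop("query genes outside universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  N <- length(collection$universe)
  q_size <- length(query)
  overlaps <- lapply(collection$sets, intersect, query)
  k <- vapply(overlaps, length, 1L)
  keep <- k >= min_overlap
  if (!any(keep))
    return(data.frame(pathway = character(), k_overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      universe_size = integer(), p = numeric(), q = numeric()))
  m <- vapply(collection$sets, length, 1L)[keep]
  kk <- k[keep]
  p <- stats::phyper(kk - 1L, m, N - m, q_size, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(pathway = names(collection$sets)[keep],
                    k_overlap = kk, set_size = m, query_size = q_size,
                    universe_size = N, p = p, q = q,
                    stringsAsFactors = FALSE)
  out$overlap_genes <- I(unname(overlaps[keep]))
  out <- out[out$q <= q_max, , drop = FALSE]
  out <- out[order(out$q, out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binary pathway x gene membership matrix of enrichment results
#'
#' @param results data.frame from [overlap_enrichment()].
#' @return binary matrix; rows = pathways, columns = union of overlap genes,
#'   entry 1 iff the gene is in the pathway's overlap.
#' @export
membership_matrix <- function(results) {
  if (nrow(results) == 0L) stop("no enrichment results")
  genes <- sort(unique(unlist(results$overlap_genes)))
  M <- matrix(0L, nrow(results), length(genes),
              dimnames = list(results$pathway, genes))
  for (i in seq_len(nrow(results)))
    M[i, results$overlap_genes[[i]]] <- 1L
  M
}

#' Two-way clustering of the pathway x gene membership matrix
#'
#' Agglomerative clustering of rows (pathways) and columns (genes)
#' independently, Minkowski distance with Ward linkage. Meta-clusters are
#' contiguous row blocks obtained by cutting the row dendrogram.
#'
#' @param M binary membership matrix from [membership_matrix()].
#' @param minkowski_p Minkowski exponent (default 2 = Euclidean).
#' @param n_meta number of meta-clusters to cut the row tree into
#'   (default 2); alternatively give `h_meta`, a cut height.
#' @param h_meta optional cut height overriding `n_meta`.
#' @return list with `row_tree`, `col_tree` (hclust objects), `row_order`,
#'   `col_order`, and `meta` (meta-cluster label per pathway).
#' @export
cluster_pathway_gene <- function(M, minkowski_p = 2, n_meta = 2L,
                                 h_meta = NULL) {
  if (nrow(M) < 2L || ncol(M) < 2L) stop("need at least 2 rows and 2 columns")
  if (all(M == M[1L, 1L]) ||
      all(apply(M, 1L, function(r) identical(r, M[1L, ]))))
    warning("degenerate membership matrix: all rows identical")
  rd <- stats::dist(M, method = "minkowski", p = minkowski_p)
  cd <- stats::dist(t(M), method = "minkowski", p = minkowski_p)
  row_tree <- stats::hclust(rd, method = "ward.D2")
  col_tree <- stats::hclust(cd, method = "ward.D2")
  meta <- if (is.null(h_meta)) stats::cutree(row_tree, k = min(n_meta, nrow(M)))
          else stats::cutree(row_tree, h = h_meta)
  list(row_tree = row_tree, col_tree = col_tree,
       row_order = row_tree$order, col_order = col_tree$order,
       meta = meta)
}

#' Per-gene clinical response statistics
#'
#' The per-gene score underlying pathway fitness: either the Welch t-statistic
#' comparing expression between the responder tail (upper `tail_fraction` of
#' months to progression) and the non-responder tail (lower tail), or the
#' Pearson correlation of expression with months to progression.
#'
#' @param clin_expr patients x genes matrix.
#' @param response clinical response table.
#' @param mode `"ttest_quantile"` (default) or `"correlation"`.
#' @param tail_fraction tail size for the t-test mode (default 0.20).
#' @return data.frame with `gene`, `stat` (responder minus non-responder),
#'   `p`, `direction`, `degenerate` flag.
#' @export
gene_response_statistic <- function(clin_expr, response,
                                    mode = c("ttest_quantile", "correlation"),
                                    tail_fraction = 0.20) {
  mode <- match.arg(mode)
  clin_expr <- as_expression_matrix(clin_expr)
  resp <- response$response[match(rownames(clin_expr), response$sample_id)]
  if (anyNA(resp)) stop("response missing for some patients")
  n <- length(resp)
  if (mode == "ttest_quantile") {
    k <- floor(tail_fraction * n)
    if (k < 3L) stop("need at least 3 patients per tail")
    if (2L * k > n) stop("tails overlap: tail_fraction too large")
    ord <- order(resp)
    nonresp <- ord[seq_len(k)]
    respd <- ord[seq.int(n - k + 1L, n)]
    wt <- welch_t_columns(clin_expr[respd, , drop = FALSE],
                          clin_expr[nonresp, , drop = FALSE])
    stat <- unname(wt$t); p <- unname(wt$p)
    degenerate <- stat == 0 & p == 1
  } else {
    if (n < 3L) stop("need at least 3 patients")
    sds <- apply(clin_expr, 2L, stats::sd)
    degenerate <- sds == 0
    stat <- rep(0, ncol(clin_expr)); p <- rep(1, ncol(clin_expr))
    ok <- !degenerate
    r <- drop(stats::cor(clin_expr[, ok, drop = FALSE], resp))
    tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r * r, .Machine$double.eps))
    stat[ok] <- r
    p[ok] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  data.frame(gene = colnames(clin_expr), stat = stat, p = p,
             direction = ifelse(stat >= 0, "over-in-responders",
                                "over-in-nonresponders"),
             degenerate = degenerate, stringsAsFactors = FALSE)
}

# Tie-corrected Kruskal-Wallis statistic for the two-group split defined by
# `in_group` over `values`, signed by the comparison of group means.
.kw_signed <- function(values, in_group) {
  N <- length(values)
  rk <- rank(values)
  n1 <- sum(in_group); n2 <- N - n1
  r1 <- mean(rk[in_group]); r2 <- mean(rk[!in_group])
  H <- 12 / (N * (N + 1)) *
    (n1 * (r1 - (N + 1) / 2)^2 + n2 * (r2 - (N + 1) / 2)^2)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (correction > 0) H <- H / correction
  sgn <- if (mean(values[in_group]) > mean(values[!in_group])) 1 else -1
  list(statistic = H, signed = sgn * H,
       p = stats::pchisq(H, df = 1L, lower.tail = FALSE))
}

#' Signed pathway fitness score H
#'
#' The per-gene response statistics of in-pathway and out-of-pathway genes
#' are compared as two sample populations with the tie-corrected
#' Kruskal-Wallis rank statistic. H carries the sign of the comparison:
#' positive when in-pathway genes are, on average, over-expressed in
#' responders (their statistics exceed the out-of-pathway mean), negative
#' otherwise. Pathways scoring fewer than `min_genes` genes get H = 0.
#'
#' @param stats data.frame from [gene_response_statistic()] covering the
#'   scored gene universe.
#' @param pathway_genes character vector of the pathway's genes.
#' @param min_genes minimum scored in-pathway genes for a nonzero H
#'   (default 5).
#' @return list with `H` (signed), `kw_statistic`, `kw_p`,
#'   `n_pathway_genes_scored`.
#' @export
pathway_fitness <- function(stats, pathway_genes, min_genes = 5L) {
  in_group <- stats$gene %in% pathway_genes
  n_in <- sum(in_group)
  if (n_in == nrow(stats))
    stop("pathway covers the whole scored universe: no out-group")
  if (n_in < min_genes)
    return(list(H = 0, kw_statistic = 0, kw_p = 1,
                n_pathway_genes_scored = n_in))
  kw <- .kw_signed(stats$stat, in_group)
  list(H = kw$signed, kw_statistic = kw$statistic, kw_p = kw$p,
       n_pathway_genes_scored = n_in)
}

#' Leave-one-out gene contributions to pathway fitness
#'
#' For every pathway and every scored gene in it, recomputes H without that
#' gene; the gene's contribution to that pathway is `H - H_without_gene`.
#' A gene's delta(fitness) is the mean contribution over all supplied
#' pathways containing it. Genes whose clinical response statistic has
#' p > `p_max` are excluded from the reported ranking.
#'
#' @param stats data.frame from [gene_response_statistic()].
#' @param pathways named list of gene vectors (typically the overlap genes of
#'   the enriched pathways, see [overlap_enrichment()]).
#' @param p_max response-significance cutoff for reporting (default 0.2).
#' @param min_genes passed to [pathway_fitness()].
#' @return list with `fitness` (data.frame pathway, H, kw_p, n_genes),
#'   `contributions` (data.frame pathway, gene, delta), and `gene_table`
#'   (data.frame gene, delta = mean contribution, sum_H = summed H of
#'   contributing pathways, n_pathways, stat, p), restricted to p <= p_max
#'   and sorted by delta.
#' @export
delta_fitness <- function(stats, pathways, p_max = 0.2, min_genes = 5L) {
  if (length(pathways) == 0L) stop("no pathways supplied")
  if (is.null(names(pathways))) stop("pathways must be named")
  fit_rows <- vector("list", length(pathways))
  contrib <- vector("list", length(pathways))
  for (i in seq_along(pathways)) {
    pw <- names(pathways)[i]
    fit <- pathway_fitness(stats, pathways[[i]], min_genes = min_genes)
    fit_rows[[i]] <- data.frame(pathway = pw, H = fit$H, kw_p = fit$kw_p,
                                n_genes = fit$n_pathway_genes_scored,
                                stringsAsFactors = FALSE)
    scored <- intersect(pathways[[i]], stats$gene)
    if (length(scored) == 0L) next
    deltas <- vapply(scored, function(g) {
      reduced <- stats[stats$gene != g, , drop = FALSE]
      fit$H - pathway_fitness(reduced, setdiff(pathways[[i]], g),
                              min_genes = min_genes)$H
    }, 1)
    contrib[[i]] <- data.frame(pathway = pw, gene = scored,
                               delta = unname(deltas), H = fit$H,
                               stringsAsFactors = FALSE)
  }
  fitness <- do.call(rbind, fit_rows)
  contributions <- do.call(rbind, contrib)
  rownames(fitness) <- rownames(contributions) <- NULL
  by_gene <- split(contributions, contributions$gene)
  gene_table <- do.call(rbind, lapply(by_gene, function(d)
    data.frame(gene = d$gene[1L], delta = mean(d$delta), sum_H = sum(d$H),
               n_pathways = nrow(d),
               pathways = paste(d$pathway, collapse = ";"),
               stringsAsFactors = FALSE)))
  idx <- match(gene_table$gene, stats$gene)
  gene_table$stat <- stats$stat[idx]
  gene_table$p <- stats$p[idx]
  gene_table <- gene_table[gene_table$p <= p_max, , drop = FALSE]
  gene_table <- gene_table[order(-gene_table$delta, gene_table$gene), ,
                           drop = FALSE]
  rownames(gene_table) <- NULL
  list(fitness = fitness, contributions = contributions,
       gene_table = gene_table)
}
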