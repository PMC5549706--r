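#' Build the pathway-gene biomarker network
#'
#' Pathways in the upper and lower `pct` percentile tails of the (nonzero,
#' signed) fitness scores contribute a clique over their genes, with edge
#' weight equal to the pathway's H. Duplicate gene pairs are deduplicated,
#' keeping the provenance of the pathway with the largest |H|.
#'
#' @param fitness data.frame with columns `pathway` and `H` (see
#'   [delta_fitness()]).
#' @param pathways named list mapping pathway name to its genes (typically
#'   the enrichment overlap genes).
#' @param gene_attrs optional data.frame with columns `gene`, `delta`,
#'   `stat` (from [delta_fitness()]'s `gene_table`) used for node attributes.
#' @param pct percentile tail of the fitness scores (default 0.20).
#' @return list of class `biomarker_network` with `nodes` and `edges`
#'   data.frames.
#' @export
build_network <- function(fitness, pathways, gene_attrs = NULL, pct = 0.20) {
  fitness <- fitness[fitness$H != 0, , drop = FALSE]
  if (nrow(fitness) == 0L) stop("no pathway with nonzero fitness")
  hi <- stats::quantile(fitness$H, 1 - pct, names = FALSE)
  lo <- stats::quantile(fitness$H, pct, names = FALSE)
  keep <- fitness[fitness$H >= hi | fitness$H <= lo, , drop = FALSE]
  if (nrow(keep) == 0L) stop("no pathway survives the percentile filter")
  edges <- list()
  for (i in seq_len(nrow(keep))) {
    pw <- keep$pathway[i]
    genes <- sort(unique(pathways[[pw]]))
    if (length(genes) < 2L) next
    pairs <- utils::combn(genes, 2L)
    edges[[length(edges) + 1L]] <-
      data.frame(gene_a = pairs[1L, ], gene_b = pairs[2L, ],
                 weight = keep$H[i], pathway = pw, stringsAsFactors = FALSE)
  }
  if (length(edges) == 0L) stop("no pathway with at least 2 genes survives")
  edges <- do.call(rbind, edges)
  key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
  edges <- edges[order(key, -abs(edges$weight)), , drop = FALSE]
  edges <- edges[!duplicated(paste(edges$gene_a, edges$gene_b, sep = "\r")), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  nodes <- data.frame(gene = genes, selected = FALSE,
                      direction = NA_character_, delta = NA_real_,
                      stringsAsFactors = FALSE)
  if (!is.null(gene_attrs)) {
    idx <- match(nodes$gene, gene_attrs$gene)
    nodes$selected <- !is.na(idx)
    nodes$delta <- gene_attrs$delta[idx]
    nodes$direction <- ifelse(is.na(idx), NA_character_,
                              ifelse(gene_attrs$stat[idx] >= 0,
                                     "over-in-responders",
                                     "over-in-nonresponders"))
  }
  structure(list(nodes = nodes, edges = edges), class = "biomarker_network")
}

#' @export
print.biomarker_network <- function(x, ...) {
  cat("Biomarker network:", nrow(x$nodes), "genes,", nrow(x$edges),
      "edges from", length(unique(x$edges$pathway)), "pathways\n")
  invisible(x)
}

#' Export a biomarker network to SIF or GraphML
#'
#' SIF writes `geneA pathway_weight geneB` lines plus node and edge attribute
#' sidecar tables (`<path>.nodes.tsv`, `<path>.edges.tsv`). GraphML carries
#' the attributes inline and loads in standard network viewers.
#'
#' @param net [build_network()] result.
#' @param path output file.
#' @param format `"sif"` or `"graphml"`.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (nrow(net$edges) == 0L) stop("empty network")
  if (format == "sif") {
    writeLines(paste(net$edges$gene_a, "pathway_weight", net$edges$gene_b),
               path)
    utils::write.table(net$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(net$edges, paste0(path, ".edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    doc <- xml2::xml_new_root("graphml",
                              xmlns = "http://graphml.graphdrawing.org/xmlns")
    for (k in list(c("d_weight", "edge", "weight", "double"),
                   c("d_pathway", "edge", "pathway", "string"),
                   c("d_selected", "node", "selected", "boolean"),
                   c("d_direction", "node", "direction", "string"),
                   c("d_delta", "node", "delta", "double"))) {
      xml2::xml_add_child(doc, "key", id = k[1L], `for` = k[2L],
                          attr.name = k[3L], attr.type = k[4L])
    }
    g <- xml2::xml_add_child(doc, "graph", id = "biomarkers",
                             edgedefault = "undirected")
    for (i in seq_len(nrow(net$nodes))) {
      nd <- xml2::xml_add_child(g, "node", id = net$nodes$gene[i])
      xml2::xml_add_child(nd, "data", key = "d_selected",
                          tolower(as.character(net$nodes$selected[i])))
      if (!is.na(net$nodes$direction[i]))
        xml2::xml_add_child(nd, "data", key = "d_direction",
                            net$nodes$direction[i])
      if (!is.na(net$nodes$delta[i]))
        xml2::xml_add_child(nd, "data", key = "d_delta",
                            format(net$nodes$delta[i], digits = 17))
    }
    for (i in seq_len(nrow(net$edges))) {
      ed <- xml2::xml_add_child(g, "edge", source = net$edges$gene_a[i],
                                target = net$edges$gene_b[i])
      xml2::xml_add_child(ed, "data", key = "d_weight",
                          format(net$edges$weight[i], digits = 17))
      xml2::xml_add_child(ed, "data", key = "d_pathway", net$edges$pathway[i])
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Clustered pairwise-correlation matrix of network genes
#'
#' Pairwise Pearson correlations of the supplied gene expressions, with rows
#' and columns ordered by Euclidean-distance Ward clustering of the
#' correlation matrix. Constant genes get NA correlations and a warning.
#'
#' @param clin_expr patients x genes matrix restricted to the network genes.
#' @param path optional TSV output path (first column = gene, second = group
#'   label, then the correlation columns in cluster order).
#' @param negative_genes genes to label as belonging to negative-fitness
#'   pathways in the output table.
#' @return the reordered correlation matrix (invisibly if `path` is given).
#' @export
export_correlation_matrix <- function(clin_expr, path = NULL,
                                      negative_genes = character()) {
  clin_expr <- as.matrix(clin_expr)
  if (ncol(clin_expr) < 2L) stop("need at least 2 genes")
  constant <- apply(clin_expr, 2L, stats::sd) == 0
  if (any(constant))
    warning("constant gene(s), correlations undefined: ",
            paste(colnames(clin_expr)[constant], collapse = ", "))
  cm <- suppressWarnings(stats::cor(clin_expr))
  ok <- !constant
  ord <- seq_len(ncol(cm))
  if (sum(ok) >= 2L) {
    tree <- stats::hclust(stats::dist(cm[ok, ok, drop = FALSE]),
                          method = "ward.D2")
    ord <- c(which(ok)[tree$order], which(!ok))
  }
  cm <- cm[ord, ord, drop = FALSE]
  if (!is.null(path)) {
    tab <- data.frame(gene = rownames(cm),
                      group = ifelse(rownames(cm) %in% negative_genes,
                                     "negative_fitness", "positive_fitness"),
                      cm, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = NA),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(cm))
  }
  cm
}
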