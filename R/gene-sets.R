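#' Construct a gene-set collection restricted to a gene universe
#'
#' Each set is intersected with the universe; sets retaining fewer than
#' `min_genes` members are dropped (overlap enrichment needs at least 2
#' shared genes to be meaningful).
#'
#' @param sets named list of character vectors (pathway name -> genes).
#' @param universe character vector of admissible gene ids.
#' @param min_genes minimum post-intersection set size to retain.
#' @return object of class `gene_set_collection`: list with `sets` (named
#'   list), `universe`, and `n_dropped`.
#' @export
gene_set_collection <- function(sets, universe, min_genes = 2L) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene sets must have unique names")
  universe <- unique(as.character(universe))
  trimmed <- lapply(sets, function(g) intersect(unique(as.character(g)), universe))
  keep <- vapply(trimmed, length, 1L) >= min_genes
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(n_dropped, " gene set(s) dropped (fewer than ", min_genes,
            " genes in universe)")
  structure(list(sets = trimmed[keep], universe = universe,
                 n_dropped = n_dropped),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$sets, length, 1L)
  cat("Gene-set collection:", length(x$sets), "sets over",
      length(x$universe), "universe genes\n")
  if (length(sizes))
    cat("  set sizes:", min(sizes), "-", max(sizes),
        " (total memberships ", sum(sizes), ")\n", sep = "")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard Broad GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file.
#' @param universe gene ids the collection is restricted to.
#' @param min_genes minimum post-intersection size (default 2).
#' @return [gene_set_collection()] object.
#' @export
read_gene_sets <- function(path, universe, min_genes = 2L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    stop("malformed GMT line ", short[1L], ": fewer than 3 fields")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set name: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  gene_set_collection(sets, universe, min_genes = min_genes)
}

#' Write gene sets to a GMT file
#' @param collection [gene_set_collection()] object or named list of gene sets.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gene_sets <- function(collection, path, descriptions = NULL) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(name, desc, genes)
    paste(c(name, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}
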