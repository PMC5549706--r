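#' Configuration for the synthetic preclinical + clinical generator
#'
#' The generator emulates the statistical structure the screen assumes: two
#' expression matrices over a shared gene universe, a planted driver-gene
#' signature that linearly drives both IC50 (preclinical) and months to
#' progression (clinical, with a negative link so predicted chemosensitivity
#' anti-correlates with survival), tissue labels, and gene sets some of which
#' contain the planted signature.
#'
#' Structural choices: expressions are marginally standard normal; signature
#' genes share a latent per-sample driver factor with correlation
#' `signature_rho` (co-regulated driver program), and every gene carries a
#' weak loading `global_loading` on that factor, emulating the global
#' expression programs of real transcriptome data that make the mean
#' expression of a random gene subset weakly informative.
#'
#' @param n_genes,n_cells,n_patients dataset dimensions.
#' @param n_pathways number of gene sets; `pathway_size_range` their sizes.
#' @param signature_size number of planted driver genes.
#' @param effect_size signal strength of the clinical link (the preclinical
#'   link has unit strength).
#' @param noise_sd residual standard deviation of both response links.
#' @param n_tissues number of tissue labels, drawn uniformly per cell.
#' @param sign_split fraction of signature genes with positive weight.
#' @param signature_rho within-signature latent-factor correlation.
#' @param global_loading latent-factor loading of non-signature genes.
#' @param n_planted number of pathways planted with >= `planted_overlap`
#'   same-sign signature genes.
#' @param planted_overlap signature genes per planted pathway.
#' @param tissue_enrichment if TRUE, the most drug-sensitive cells are biased
#'   toward the first tissue label (for testing Fisher enrichment under the
#'   alternative).
#' @param clinical_scale multiplicative scale of the clinical expression
#'   platform relative to the preclinical one. The method runs on unscaled
#'   cross-platform data, and the clinical platform's larger per-gene spread
#'   is what lets out-of-sample patient scores span a range comparable to the
#'   in-sample predictions (the 80% range rule); correlation- and rank-based
#'   statistics are unaffected by this factor.
#' @param pfs_center location of the months-to-progression scale.
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_cells = 120L, n_patients = 30L,
                       n_pathways = 80L, pathway_size_range = c(10L, 40L),
                       signature_size = 30L, effect_size = 1.5,
                       noise_sd = 0.5, n_tissues = 5L, sign_split = 0.5,
                       signature_rho = 0.4, global_loading = 0.02,
                       n_planted = 6L, planted_overlap = 10L,
                       tissue_enrichment = FALSE, clinical_scale = 3,
                       pfs_center = 12, seed = 1L) {
  stopifnot(signature_size <= n_genes, effect_size >= 0, noise_sd > 0,
            sign_split >= 0, sign_split <= 1,
            signature_rho >= 0, signature_rho < 1,
            length(pathway_size_range) == 2L)
  if (pathway_size_range[2L] > n_genes)
    stop("pathway_size_range infeasible for n_genes")
  structure(as.list(environment()), class = "sim_config")
}

# Draw a samples x genes matrix where gene g = loading_g * z + noise,
# marginally standard normal.
.sim_expression <- function(n_samples, loadings, z) {
  n_genes <- length(loadings)
  E <- matrix(stats::rnorm(n_samples * n_genes), n_samples, n_genes)
  E <- sweep(E, 2L, sqrt(1 - loadings^2), `*`)
  E + outer(z, loadings)
}

#' Generate a synthetic dataset with a planted shared signature
#'
#' @param config [sim_config()].
#' @return list of class `synthetic_dataset` with elements `preclinical`
#'   (`expr`, `response`), `clinical` (`expr`, `response`), `gene_sets`, and
#'   `truth` (signature genes with weights and signs, planted pathway names).
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  cells <- sprintf("cell%03d", seq_len(config$n_cells))
  patients <- sprintf("pt%03d", seq_len(config$n_patients))

  S <- config$signature_size
  sig_genes <- sort(sample(genes, S))
  n_pos <- round(config$sign_split * S)
  sign_vec <- sample(c(rep(1, n_pos), rep(-1, S - n_pos)))
  w <- sign_vec * stats::runif(S, 0.5, 1.5) / sqrt(S)

  loadings <- rep(config$global_loading, config$n_genes)
  names(loadings) <- genes
  loadings[sig_genes] <- sqrt(config$signature_rho) * sign_vec

  z_cell <- stats::rnorm(config$n_cells)
  E_cell <- .sim_expression(config$n_cells, loadings, z_cell)
  dimnames(E_cell) <- list(cells, genes)
  score_cell <- drop(E_cell[, sig_genes, drop = FALSE] %*% w)
  ic50 <- score_cell + stats::rnorm(config$n_cells, sd = config$noise_sd)

  z_pat <- stats::rnorm(config$n_patients)
  E_pat <- .sim_expression(config$n_patients, loadings, z_pat)
  dimnames(E_pat) <- list(patients, genes)
  score_pat <- drop(E_pat[, sig_genes, drop = FALSE] %*% w)
  pfs <- config$pfs_center - config$effect_size * score_pat +
    stats::rnorm(config$n_patients, sd = config$noise_sd)
  E_pat <- config$clinical_scale * E_pat

  tissues <- paste0("tissue", sample.int(config$n_tissues, config$n_cells,
                                         replace = TRUE))
  if (config$tissue_enrichment) {
    sensitive <- rank(ic50) <= ceiling(config$n_cells / 4)
    biased <- sensitive & stats::runif(config$n_cells) < 0.7
    tissues[biased] <- "tissue1"
  }

  sets <- vector("list", config$n_pathways)
  names(sets) <- sprintf("PW%03d", seq_len(config$n_pathways))
  pos_sig <- sig_genes[sign_vec > 0]
  neg_sig <- sig_genes[sign_vec < 0]
  for (i in seq_len(config$n_pathways)) {
    size <- sample(seq(config$pathway_size_range[1L],
                       config$pathway_size_range[2L]), 1L)
    if (i <= config$n_planted) {
      pool <- if (i %% 2L == 1L) pos_sig else neg_sig
      k <- min(config$planted_overlap, length(pool))
      core <- sample(pool, k)
      filler <- sample(setdiff(genes, sig_genes), max(size - k, 0L))
      sets[[i]] <- c(core, filler)
    } else {
      sets[[i]] <- sample(setdiff(genes, sig_genes), size)
    }
  }
  planted <- names(sets)[seq_len(config$n_planted)]

  structure(list(
    preclinical = list(expr = as_expression_matrix(E_cell),
                       response = response_table(cells, ic50, tissue = tissues)),
    clinical = list(expr = as_expression_matrix(E_pat),
                    response = response_table(patients, pfs)),
    gene_sets = suppressMessages(gene_set_collection(sets, genes)),
    truth = list(signature = data.frame(gene = sig_genes, weight = w,
                                        sign = sign_vec,
                                        stringsAsFactors = FALSE),
                 planted_pathways = planted),
    config = config), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", x$config$n_genes, "genes;",
      x$config$n_cells, "cells,", x$config$n_patients, "patients\n")
  cat("  planted signature:", nrow(x$truth$signature), "genes (",
      sum(x$truth$signature$sign > 0), "positive /",
      sum(x$truth$signature$sign < 0), "negative )\n")
  cat("  gene sets:", length(x$gene_sets$sets), "(planted:",
      paste(x$truth$planted_pathways, collapse = ", "), ")\n")
  invisible(x)
}

#' Permute the clinical response of a synthetic dataset
#'
#' Months to progression is permuted uniformly among patients; expressions
#' are untouched. This is the null configuration of the screen: a campaign on
#' permuted data should accept no models.
#'
#' @param data `synthetic_dataset`.
#' @param seed permutation seed.
#' @return the dataset with permuted clinical response.
#' @export
permute_clinical_response <- function(data, seed = 1L) {
  stopifnot(inherits(data, "synthetic_dataset"))
  set.seed(seed)
  resp <- data$clinical$response
  resp$response <- sample(resp$response)
  data$clinical$response <- resp
  data
}
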