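test_that("overlap enrichment equals the exact tail sum and filters overlaps", {
  universe <- paste0("g", 1:100)
  col <- suppressMessages(gene_set_collection(
    list(hit = paste0("g", 1:10),        # overlap 5 with query
         low = paste0("g", c(1, 50:57)), # overlap 1 -> excluded
         none = paste0("g", 60:69)),     # overlap 0 -> excluded
    universe))
  query <- paste0("g", c(1:5, 90:94))
  res <- overlap_enrichment(query, col, q_max = Inf, min_overlap = 2L)
  expect_identical(res$pathway, "hit")
  expect_equal(res$p, oracle_hyper_tail(5, 10, 100, 10), tolerance = 1e-12)
  expect_identical(sort(res$overlap_genes[[1]]), paste0("g", 1:5))

  # query equal to one pathway attains that pathway's minimal p
  res2 <- overlap_enrichment(paste0("g", 1:10), col, q_max = Inf)
  expect_equal(res2$p[res2$pathway == "hit"],
               oracle_hyper_tail(10, 10, 100, 10), tolerance = 1e-12)

  expect_error(overlap_enrichment(character(0), col), "empty query")
  expect_error(overlap_enrichment("not_in_universe", col), "outside universe")
})

test_that("BH adjustment is monotone in p-rank and bounded below by p", {
  set.seed(2)
  universe <- paste0("g", 1:400)
  sets <- lapply(1:25, function(i) sample(universe, sample(10:40, 1)))
  names(sets) <- paste0("pw", 1:25)
  col <- suppressMessages(gene_set_collection(sets, universe))
  res <- overlap_enrichment(sample(universe, 60), col, q_max = Inf)
  expect_true(all(res$q >= res$p))
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
})

test_that("membership matrix mirrors the overlaps", {
  res <- data.frame(pathway = c("a", "b"), stringsAsFactors = FALSE)
  res$overlap_genes <- I(list(c("g1", "g2", "g3"), c("g1")))
  res$k_overlap <- c(3L, 1L)
  M <- membership_matrix(res)
  expect_identical(dim(M), c(2L, 3L))
  expect_equal(sort(unname(colSums(M)), decreasing = TRUE), c(2, 1, 1))
  expect_equal(unname(rowSums(M)), as.numeric(res$k_overlap))

  single <- data.frame(pathway = "a", stringsAsFactors = FALSE)
  single$overlap_genes <- I(list(c("g1", "g2")))
  expect_true(all(membership_matrix(single) == 1L))
})

test_that("pathway-gene clustering matches the Lance-Williams oracle", {
  M <- matrix(c(1, 1, 0, 0,
                1, 1, 1, 0,
                0, 0, 1, 1,
                0, 1, 1, 1,
                1, 0, 0, 0), 5, 4, byrow = TRUE,
              dimnames = list(paste0("pw", 1:5), paste0("g", 1:4)))
  res <- cluster_pathway_gene(M, n_meta = 2L)
  oracle <- oracle_ward(dist(M, method = "minkowski", p = 2))
  expect_equal(sort(res$row_tree$height), sort(oracle$heights),
               tolerance = 1e-10)
  got <- hclust_merge_sets(res$row_tree)
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(oracle$merges, paste, collapse = ","))

  # identical rows merge first at height zero
  M2 <- rbind(M, pw6 = M["pw1", ])
  res2 <- cluster_pathway_gene(M2)
  expect_equal(min(res2$row_tree$height), 0)
  expect_setequal(hclust_merge_sets(res2$row_tree)[[1]], c(1L, 6L))

  # permutation of rows leaves the merge topology invariant (real-valued
  # matrix so no pairwise distance ties confound the comparison)
  set.seed(31)
  R <- matrix(rnorm(20), 5, 4, dimnames = dimnames(M))
  res_r <- cluster_pathway_gene(R, n_meta = 2L)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  res_p <- cluster_pathway_gene(R[perm, ], n_meta = 2L)
  relabel <- function(sets, p) lapply(sets, function(s) sort(p[s]))
  expect_setequal(
    lapply(relabel(hclust_merge_sets(res_p$row_tree), perm),
           paste, collapse = ","),
    lapply(hclust_merge_sets(res_r$row_tree), paste, collapse = ","))

  expect_warning(cluster_pathway_gene(matrix(1, 3, 3)), "degenerate")
})

test_that("gene response statistics cover both modes consistently", {
  set.seed(1)
  n <- 15
  expr <- matrix(rnorm(n * 4), n, 4,
                 dimnames = list(paste0("p", 1:n),
                                 c("up", "down", "null", "flat")))
  resp <- response_table(paste0("p", 1:n), seq_len(n) + rnorm(n, sd = 0.01))
  expr[, "up"] <- resp$response + rnorm(n, sd = 0.3)
  expr[, "down"] <- -resp$response + rnorm(n, sd = 0.3)
  expr[, "flat"] <- 5

  tt <- gene_response_statistic(expr, resp, mode = "ttest_quantile",
                                tail_fraction = 0.2)
  expect_gt(tt$stat[tt$gene == "up"], 2)
  expect_identical(tt$direction[tt$gene == "up"], "over-in-responders")
  expect_lt(tt$stat[tt$gene == "down"], -2)
  expect_true(tt$degenerate[tt$gene == "flat"])
  expect_equal(tt$p[tt$gene == "flat"], 1)

  cc <- gene_response_statistic(expr, resp, mode = "correlation")
  ct <- pearson_with_pvalue(expr[, "up"], resp$response)
  expect_equal(cc$stat[cc$gene == "up"], ct$r)
  expect_equal(log(cc$p[cc$gene == "up"]), ct$ln_p, tolerance = 1e-8)
  # both modes agree on the sign of a planted gene
  expect_identical(sign(cc$stat[cc$gene == "down"]),
                   sign(tt$stat[tt$gene == "down"]))
})

test_that("pathway fitness reproduces the rank-formula value and the 5-gene rule", {
  stats <- data.frame(gene = paste0("g", 1:10),
                      stat = c(1:5 / 10, 6:10),   # in-pathway ranks 6..10
                      p = rep(0.01, 10), stringsAsFactors = FALSE)
  pw <- paste0("g", 6:10)
  fit <- pathway_fitness(stats, pw)
  expect_equal(fit$kw_statistic, 12 / (10 * 11) *
                 (5 * (8 - 5.5)^2 + 5 * (3 - 5.5)^2), tolerance = 1e-12)
  expect_equal(fit$H, fit$kw_statistic)   # in-pathway stats are larger
  expect_equal(fit$kw_statistic,
               unname(kruskal.test(stats$stat,
                                   factor(stats$gene %in% pw))$statistic),
               tolerance = 1e-12)

  # four scored genes give a hard zero
  expect_equal(pathway_fitness(stats, paste0("g", 1:4))$H, 0)

  # perfectly interleaved ranks are close to null
  inter <- data.frame(gene = paste0("g", 1:10), stat = 1:10,
                      p = 0.01, stringsAsFactors = FALSE)
  fit_i <- pathway_fitness(inter, paste0("g", c(1, 3, 5, 7, 9)))
  expect_lt(abs(fit_i$kw_statistic), 0.5)

  expect_error(pathway_fitness(stats, stats$gene), "out-group")
})

test_that("H is rank-invariant, sign-antisymmetric, and tie-corrected", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(12:40, 1)
    vals <- sample(c(rnorm(n - 4), rep(0.5, 4)))  # force some ties
    genes <- paste0("g", seq_len(n))
    stats <- data.frame(gene = genes, stat = vals, p = 0.01,
                        stringsAsFactors = FALSE)
    pw <- sample(genes, sample(5:(n - 2), 1))
    fit <- pathway_fitness(stats, pw)
    expect_equal(fit$kw_statistic, oracle_kw(vals, genes %in% pw),
                 tolerance = 1e-10)
    expect_equal(abs(fit$H), fit$kw_statistic)

    # strictly monotone transform preserves |H|
    trans <- stats; trans$stat <- exp(2 * trans$stat) + 1
    expect_equal(abs(pathway_fitness(trans, pw)$H), abs(fit$H),
                 tolerance = 1e-10)

    # negating every statistic flips the sign
    neg <- stats; neg$stat <- -neg$stat
    expect_equal(pathway_fitness(neg, pw)$H, -fit$H, tolerance = 1e-10)
  }
})

test_that("leave-one-out deltas equal brute-force recomputation", {
  set.seed(4)
  genes <- paste0("g", 1:20)
  stats <- data.frame(gene = genes, stat = rnorm(20), p = runif(20, 0, 0.15),
                      stringsAsFactors = FALSE)
  pathways <- list(pwA = paste0("g", 1:6), pwB = paste0("g", c(4:8, 15)))
  res <- delta_fitness(stats, pathways, p_max = 0.2)
  for (i in seq_len(nrow(res$contributions))) {
    row <- res$contributions[i, ]
    full <- pathway_fitness(stats, pathways[[row$pathway]])$H
    reduced <- pathway_fitness(stats[stats$gene != row$gene, ],
                               setdiff(pathways[[row$pathway]], row$gene))$H
    expect_equal(row$delta, full - reduced, tolerance = 1e-12)
  }
  # a gene in both pathways averages its two contributions
  shared <- intersect(pathways$pwA, pathways$pwB)
  for (g in shared) {
    both <- res$contributions$delta[res$contributions$gene == g]
    expect_equal(res$gene_table$delta[res$gene_table$gene == g], mean(both))
  }
})

test_that("genes with weak response statistics are excluded from the ranking", {
  genes <- paste0("g", 1:12)
  stats <- data.frame(gene = genes, stat = c(6:12, 1:5) / 2,
                      p = c(rep(0.01, 11), 0.5), stringsAsFactors = FALSE)
  res <- delta_fitness(stats, list(pw = paste0("g", c(1:4, 12))), p_max = 0.2)
  expect_false("g12" %in% res$gene_table$gene)
  expect_true("g12" %in% res$contributions$gene)
})
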