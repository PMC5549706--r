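test_that("panel selection keeps the percentile tails and routes pools", {
  tab <- data.frame(gene = paste0("g", 1:5),
                    delta = c(1.0, 0.5, 0.1, -0.2, -0.8),
                    sum_H = c(3, 4, 1, -2, -5),
                    p = rep(0.01, 5), stringsAsFactors = FALSE)
  panel <- select_biomarkers(tab, p_max = 0.2, pct = 0.40)
  expect_setequal(panel$genes, c("g1", "g2", "g4", "g5"))
  expect_setequal(panel$positive_pool, c("g1", "g2"))
  expect_setequal(panel$negative_pool, c("g4", "g5"))

  all_weak <- tab; all_weak$p <- 0.5
  expect_message(empty <- select_biomarkers(all_weak), "empty panel")
  expect_length(empty$genes, 0L)
})

test_that("expression clustering matches the Ward oracle and tests clades", {
  set.seed(12)
  expr <- matrix(rnorm(16), 4, 4,
                 dimnames = list(paste0("p", 1:4), paste0("g", 1:4)))
  res <- cluster_expression(expr)
  oracle <- oracle_ward(dist(expr))
  expect_equal(sort(res$patient_tree$height), sort(oracle$heights),
               tolerance = 1e-10)
  expect_setequal(lapply(hclust_merge_sets(res$patient_tree),
                         paste, collapse = ","),
                  lapply(oracle$merges, paste, collapse = ","))

  # identical patients merge first
  expr2 <- rbind(expr, p5 = expr["p1", ])
  res2 <- cluster_expression(expr2)
  expect_setequal(hclust_merge_sets(res2$patient_tree)[[1]], c(1L, 5L))

  # planted clade structure separates the response
  n <- 20
  grp <- rep(c(0, 3), each = n / 2)
  expr3 <- matrix(rnorm(n * 6) + grp, n, 6,
                  dimnames = list(paste0("p", 1:n), paste0("g", 1:6)))
  resp <- response_table(paste0("p", 1:n), grp * 2 + rnorm(n, sd = 0.5))
  res3 <- cluster_expression(expr3, response = resp)
  expect_lt(res3$clade_test$p, 0.05)

  # a tiny clade skips the test with a warning
  expr4 <- expr3
  expr4[1, ] <- expr4[1, ] + 50
  expect_warning(res4 <- cluster_expression(expr4, response = resp),
                 "skipped")
  expect_null(res4$clade_test)
})

test_that("forest evaluation separates planted classes and stays calibrated", {
  set.seed(3)
  n <- 30
  classes <- factor(rep(c("responder", "nonresponder"), each = n / 2),
                    levels = c("responder", "nonresponder"))
  expr <- matrix(rnorm(n * 10), n, 10,
                 dimnames = list(paste0("p", 1:n), paste0("g", 1:10)))
  expr[classes == "responder", ] <- expr[classes == "responder", ] + 3
  ev <- rf_evaluate(expr, classes, n_trees = 200, n_seeds = 10, seed = 1)
  expect_lte(ev$responder_error, 5)
  expect_lte(ev$nonresponder_error, 5)
  expect_true(all(ev$errors >= 0 & ev$errors <= 100))
  expect_true(all(ev$auc_values >= 0 & ev$auc_values <= 1))
  expect_lt(ev$auc_vs_half_p, 0.05)

  # permuted labels give a near-chance AUC
  set.seed(4)
  null_ev <- rf_evaluate(expr, sample(classes), n_trees = 200, n_seeds = 10,
                         seed = 2)
  expect_lt(abs(null_ev$auc_mean - 0.5), 0.25)

  # degenerate forest is still well-formed
  tiny <- rf_evaluate(expr, classes, n_trees = 1, n_seeds = 1, seed = 3)
  expect_true(all(tiny$errors >= 0 & tiny$errors <= 100))

  expect_error(rf_evaluate(expr, factor(rep("a", n))), "two classes")
})

test_that("class-split optimization recovers a planted boundary", {
  set.seed(6)
  n <- 30; k_true <- 12
  resp <- response_table(paste0("p", 1:n), sort(rnorm(n), decreasing = TRUE))
  expr <- matrix(rnorm(n * 8), n, 8,
                 dimnames = list(paste0("p", 1:n), paste0("g", 1:8)))
  expr[1:k_true, ] <- expr[1:k_true, ] + 2  # top-k patients form a class
  res <- optimize_class_split(expr, resp, n_seeds = 25, n_trees = 200,
                              seed = 2)
  expect_lte(abs(res$split_k - k_true), 2)
  expect_identical(sum(res$classes == "responder"), res$split_k)

  expect_error(optimize_class_split(expr[1:5, ], resp[1:5, ]),
               "no feasible split")

  flat <- matrix(1, n, 3, dimnames = list(paste0("p", 1:n), paste0("g", 1:3)))
  expect_warning(res_flat <- optimize_class_split(flat, resp, n_seeds = 2,
                                                  n_trees = 50, seed = 1),
                 "flat|smallest")
  expect_identical(res_flat$split_k, 3L)
})

test_that("subsample sensitivity skips infeasible sizes and reports spreads", {
  set.seed(5)
  n <- 30
  classes <- factor(rep(c("responder", "nonresponder"), each = 15),
                    levels = c("responder", "nonresponder"))
  expr <- matrix(rnorm(n * 6), n, 6,
                 dimnames = list(paste0("p", 1:n), paste0("g", 1:6)))
  expr[classes == "responder", ] <- expr[classes == "responder", ] + 2
  expect_warning(res <- subsample_sensitivity(expr, classes,
                                              sizes = c(20, 2), n_rep = 3,
                                              n_trees = 100, seed = 1),
                 "infeasible")
  expect_identical(res$size, 20)
  expect_true(all(res$responder_error >= 0 & res$responder_error <= 100))
})

test_that("svd impact matches a direct decomposition and its invariances", {
  set.seed(7)
  X <- matrix(rnorm(9), 3, 3, dimnames = list(paste0("p", 1:3),
                                              paste0("g", 1:3)))
  imp <- svd_impact(X)
  sv <- svd(scale(X, center = TRUE, scale = FALSE))
  K <- which(cumsum(sv$d^2) / sum(sv$d^2) >= 0.9)[1]
  raw <- rowSums(sweep(sv$v[, 1:K, drop = FALSE]^2, 2, sv$d[1:K]^2, `*`))
  expect_equal(unname(imp), raw / sum(raw), tolerance = 1e-12)
  expect_equal(sum(imp), 1)

  # a single varying gene takes all the impact
  Y <- matrix(5, 4, 3, dimnames = list(paste0("p", 1:4), paste0("g", 1:3)))
  Y[, 2] <- rnorm(4)
  impY <- svd_impact(Y)
  expect_equal(unname(impY), c(0, 1, 0))

  # permutation equivariance and centering invariance
  X2 <- matrix(rnorm(40), 8, 5,
               dimnames = list(paste0("p", 1:8), paste0("g", 1:5)))
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(unname(svd_impact(X2[, perm])), unname(svd_impact(X2)[perm]))
  shifted <- sweep(X2, 2, c(10, -3, 0, 7, 100), `+`)
  expect_equal(svd_impact(shifted), svd_impact(X2), tolerance = 1e-10)

  expect_error(svd_impact(matrix(1, 3, 3)), "zero-variance")
})

test_that("pooled t-statistics match Welch by hand and flip under pool exchange", {
  set.seed(2)
  genes <- paste0("g", 1:8)
  expr <- matrix(rnorm(5 * 8), 5, 8,
                 dimnames = list(paste0("p", 1:5), genes))
  pos <- genes[1:4]; neg <- genes[5:8]
  # separated pools for patient 1: negative pool low, positive pool high
  expr[1, pos] <- c(2, 2.1, 1.9, 2)
  expr[1, neg] <- c(0, 0.05, -0.05, 0)
  resp <- response_table(paste0("p", 1:5), c(9, 4, 6, 2, 7))
  res <- pooled_tstat_classifier(expr, pos, neg, resp)
  expect_lt(res$t[["p1"]], -5)
  tt <- t.test(expr[2, neg], expr[2, pos])
  expect_equal(res$t[["p2"]], unname(tt$statistic), tolerance = 1e-10)

  swapped <- pooled_tstat_classifier(expr, neg, pos, resp)
  expect_equal(unname(swapped$t), -unname(res$t), tolerance = 1e-12)
  expect_equal(swapped$r, -res$r, tolerance = 1e-12)

  expect_error(pooled_tstat_classifier(expr, pos, c(pos[1], neg[1:2]), resp),
               "overlap")
  const <- expr; const[3, neg] <- 1
  res_const <- pooled_tstat_classifier(const, pos, neg, resp)
  expect_true(is.na(res_const$t[["p3"]]))
})
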