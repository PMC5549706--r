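test_that("classification values follow the mean-boundary 2x2 table", {
  res <- classification_values(c(0.1, 0.2, 0.8, 0.9), c(10, 1, 2, 1),
                               observed_direction = "survival")
  expect_equal(res$ppv, 0.5)
  expect_equal(res$npv, 1.0)

  # predicted rank exactly reversed against observed, balanced split
  res2 <- classification_values(c(1, 2, 3, 4), c(9, 8, 2, 1),
                                observed_direction = "survival")
  expect_equal(res2$ppv, 1)
  expect_equal(res2$npv, 1)

  # IC50-like direction flips the observed responders
  res3 <- classification_values(c(1, 2, 3, 4), c(1, 2, 8, 9),
                                observed_direction = "ic50")
  expect_equal(res3$ppv, 1)

  const <- classification_values(rep(2, 4), c(1, 2, 3, 4))
  expect_false(const$defined)
  expect_true(is.na(const$ppv))
})

test_that("training-model statistics match a step-by-step recomputation", {
  cells <- paste0("c", 1:5); genes <- paste0("g", 1:4); pts <- paste0("p", 1:5)
  pe <- as_expression_matrix(matrix(
    c(0.2, 1.1, -0.5, 0.7,
      -1.0, 0.3, 0.9, -0.2,
      1.5, -0.4, 0.1, 0.8,
      0.0, 0.6, -1.2, 0.4,
      -0.7, -0.9, 1.3, -0.6), 5, 4, byrow = TRUE,
    dimnames = list(cells, genes)))
  ce <- as_expression_matrix(matrix(
    c(0.5, -0.3, 0.8, 0.1,
      -0.2, 0.9, -0.6, 0.4,
      1.1, 0.2, 0.3, -0.8,
      -0.9, -0.5, 0.7, 0.6,
      0.3, 0.1, -1.0, 0.2), 5, 4, byrow = TRUE,
    dimnames = list(pts, genes)))
  ic50 <- response_table(cells, c(1.2, -0.8, 2.0, 0.3, -1.5))
  pfs <- response_table(pts, c(3, 8, 1, 10, 6))
  beta <- c(0.5, -0.3, 0.2, 0.1)
  intercept <- 0.25
  rec <- sampling_model_record(cells, genes, lambda = 1, intercept = intercept,
                               coefficients = beta,
                               pred_ic50 = drop(intercept + pe %*% beta),
                               pred_clinical = drop(intercept + ce %*% beta),
                               stats = NULL)
  st <- evaluate_training_model(rec, pe, ic50, ce, pfs, range_fraction = 0.8)

  mean_expr <- rowMeans(pe)
  ic50_ct <- cor.test(drop(intercept + pe %*% beta), mean_expr)
  expect_equal(st$r_ic50, unname(ic50_ct$estimate))
  expect_equal(st$ln_pval_ic50, log(ic50_ct$p.value), tolerance = 1e-9)

  ps <- drop(intercept + ce %*% beta)
  clin_ct <- cor.test(ps, pfs$response)
  expect_equal(st$r_clinical, unname(clin_ct$estimate))
  expect_equal(st$ln_pval_clinical, log(clin_ct$p.value), tolerance = 1e-9)

  pred_resp <- ps < mean(ps)
  obs_resp <- pfs$response > mean(pfs$response)
  expect_equal(st$ppv_clinical, mean(obs_resp[pred_resp]))
  expect_equal(st$npv_clinical, mean(!obs_resp[!pred_resp]))

  expect_identical(st$range_ok_ic50,
                   diff(range(rec$pred_ic50)) >=
                     0.8 * diff(range(ic50$response)))
  expect_identical(st$range_ok_clinical,
                   diff(range(ps)) >= 0.8 * diff(range(rec$pred_ic50)))
})

test_that("the dual filter applies every acceptance condition", {
  cfg <- campaign_config(n_samples = 1) # default screening thresholds
  ok <- list(ln_pval_ic50 = -12, ln_pval_clinical = -7, ppv_clinical = 0.5,
             npv_clinical = 0.5, range_ok_ic50 = TRUE,
             range_ok_clinical = TRUE, defined = TRUE)
  expect_true(dual_filter(ok, cfg))
  expect_false(dual_filter(modifyList(ok, list(ln_pval_ic50 = -10)), cfg))
  expect_false(dual_filter(modifyList(ok, list(ln_pval_clinical = -5)), cfg))
  expect_false(dual_filter(modifyList(ok, list(ppv_clinical = 0.4)), cfg))
  expect_false(dual_filter(modifyList(ok, list(npv_clinical = 0.44)), cfg))
  expect_false(dual_filter(modifyList(ok, list(range_ok_clinical = FALSE)),
                           cfg))
  expect_false(dual_filter(modifyList(ok, list(defined = FALSE)), cfg))
})

test_that("campaign draws are reproducible and config is validated", {
  d <- tiny_dataset(seed = 1L)
  cfg <- campaign_config(n_samples = 30, n_cells_per_model = 10L,
                         n_genes_per_model = 20L, ln_pval_ic50_max = Inf,
                         ln_pval_clinical_max = Inf, ppv_min = -1,
                         npv_min = -1, range_fraction = 0, seed = 4L)
  run <- function() run_sampling_campaign(
    d$preclinical$expr, d$preclinical$response,
    d$clinical$expr, d$clinical$response, cfg, progress_every = 0L)
  a <- run(); b <- run()
  expect_identical(a$records, b$records)
  expect_identical(a$n_accepted, 30L)

  empty <- run_sampling_campaign(
    d$preclinical$expr, d$preclinical$response,
    d$clinical$expr, d$clinical$response,
    campaign_config(n_samples = 0, n_cells_per_model = 10L,
                    n_genes_per_model = 20L), progress_every = 0L)
  expect_identical(empty$n_accepted, 0L)

  too_big <- campaign_config(n_samples = 1, n_cells_per_model = 1000L)
  expect_error(run_sampling_campaign(
    d$preclinical$expr, d$preclinical$response,
    d$clinical$expr, d$clinical$response, too_big), "exceeds")
})

test_that("acceptance is monotone when thresholds are relaxed", {
  d <- tiny_dataset(seed = 3L)
  run_at <- function(lp_ic50, lp_clin, pn) {
    cfg <- campaign_config(n_samples = 150, n_cells_per_model = 12L,
                           n_genes_per_model = 30L,
                           ln_pval_ic50_max = lp_ic50,
                           ln_pval_clinical_max = lp_clin,
                           ppv_min = pn, npv_min = pn,
                           range_fraction = 0.5, seed = 9L)
    acc <- run_sampling_campaign(d$preclinical$expr, d$preclinical$response,
                                 d$clinical$expr, d$clinical$response, cfg,
                                 progress_every = 0L)
    vapply(acc$records, function(r)
      paste(r$cell_subset, collapse = ","), "")
  }
  strict <- run_at(-4, -3, 0.45)
  relaxed <- run_at(-2, -1, 0.30)
  expect_true(all(strict %in% relaxed))
  expect_gte(length(relaxed), length(strict))
})

test_that("campaign checkpointing resumes to the identical result", {
  d <- tiny_dataset(seed = 6L)
  cfg <- campaign_config(n_samples = 40, n_cells_per_model = 10L,
                         n_genes_per_model = 20L, ln_pval_ic50_max = Inf,
                         ln_pval_clinical_max = Inf, ppv_min = -1,
                         npv_min = -1, range_fraction = 0, seed = 2L)
  args <- list(d$preclinical$expr, d$preclinical$response,
               d$clinical$expr, d$clinical$response)
  full <- do.call(run_sampling_campaign, c(args, list(cfg),
                                           progress_every = 0L))
  ckpt <- withr::local_tempfile(fileext = ".json")
  # run with checkpoints every 10 draws, then resume from a partial state
  do.call(run_sampling_campaign, c(args, list(cfg), checkpoint = ckpt,
                                   progress_every = 10L))
  state <- jsonlite::fromJSON(ckpt)
  expect_identical(state$draws_done, 40L)
  # rewind the checkpoint to draw 20 and resume
  half <- do.call(run_sampling_campaign, c(args, list(cfg), checkpoint = ckpt,
                                           progress_every = 10L))
  expect_equal(half$records, full$records)
})
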