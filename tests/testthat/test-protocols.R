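test_that("split plans partition records into near-equal folds with the stated fractions", {
  pheno <- balanced_pheno(200, 5) # 1000 records
  plan <- make_split_plan(pheno, k = 5, seed = 1, nested = TRUE)
  sizes <- lengths(purrr::map(plan$splits, "test"))
  expect_true(all(sizes == 200))
  all_test <- sort(unlist(purrr::map(plan$splits, "test")))
  expect_identical(all_test, seq_len(1000L)) # disjoint union of all records
  sp <- plan$splits[[1]]
  expect_length(sp$train, 800)
  expect_length(sp$validation, 160)
  expect_length(sp$inner_train, 640)
  expect_length(sp$inner_validation, 128)
  expect_length(sp$inner_inner_train, 512)
  expect_identical(sort(c(sp$inner_inner_train, sp$inner_validation)),
                   sp$inner_train)
  # determinism and fold balance on a non-divisible record count
  expect_identical(plan$splits, make_split_plan(pheno, 5, 1, TRUE)$splits)
  plan2 <- make_split_plan(balanced_pheno(201, 5), k = 5, seed = 2)
  expect_lte(diff(range(lengths(purrr::map(plan2$splits, "test")))), 1L)
  expect_error(make_split_plan(pheno[1:3, ], k = 5), "exceeds")
})

test_that("no test record leaks into any inner split of its own fold", {
  plan <- make_split_plan(balanced_pheno(60, 3), k = 5, seed = 7, nested = TRUE)
  for (sp in plan$splits) {
    inner <- c(sp$train, sp$inner_train, sp$validation,
               sp$inner_inner_train, sp$inner_validation)
    expect_length(intersect(sp$test, inner), 0L)
  }
})

test_that("the conventional protocol with a perfect oracle scores zero everywhere", {
  tt <- tiny_trial(n_lines = 30, n_markers = 60, n_env = 3, seed = 41,
                   include_ge = FALSE)
  plan <- make_split_plan(tt$pheno, k = 5, seed = 8)
  perfect <- oracle_learner(record_values(tt$pheno$value))
  res <- run_dl_m1(tt$pheno, tt$design, plan, learner = perfect)
  expect_true(all(res$fold_mse$mse == 0))
  # every record predicted exactly once, chosen configs come from the grid
  expect_identical(sort(res$predictions$record), seq_len(nrow(tt$pheno)))
  expect_equal(nrow(res$chosen), 5L)
  grid <- hyperparameter_grid(ncol(design_matrix(tt$design)))
  expect_true(all(res$chosen$units_multiplier %in% grid$units_multiplier))
  expect_true(all(res$final_train_sizes == round(0.8 * nrow(tt$pheno))))
})

test_that("the calibrated protocol inverts a noiseless affine bias exactly", {
  tt <- tiny_trial(n_lines = 30, n_markers = 60, n_env = 3, seed = 42,
                   include_ge = FALSE)
  plan <- make_split_plan(tt$pheno, k = 5, seed = 9, nested = TRUE)
  biased <- oracle_learner(record_values(tt$pheno$value),
                           intercept = 3, slope = 0.5)
  res <- run_dl_m2(tt$pheno, tt$design, plan, learner = biased)
  for (line in res$calibration) {
    # observed = -3/0.5 ... the line inverts y_hat = 3 + 0.5 y: slope 2, intercept -6
    expect_equal(line$slope, 2, tolerance = 1e-8)
    expect_equal(line$intercept, -6, tolerance = 1e-8)
    expect_lte(line$mse_after, line$mse_before)
  }
  expect_lt(max(res$fold_mse$mse), 1e-16)

  perfect <- oracle_learner(record_values(tt$pheno$value))
  res_id <- run_dl_m2(tt$pheno, tt$design, plan, learner = perfect)
  for (line in res_id$calibration) {
    expect_equal(line$slope, 1, tolerance = 1e-8)
    expect_equal(line$intercept, 0, tolerance = 1e-8)
  }
})

test_that("the calibrated protocol trains its final model on strictly less data", {
  tt <- tiny_trial(n_lines = 25, n_markers = 50, n_env = 2, seed = 43,
                   include_ge = FALSE)
  plan <- make_split_plan(tt$pheno, k = 5, seed = 10, nested = TRUE)
  perfect <- oracle_learner(record_values(tt$pheno$value))
  m1 <- run_dl_m1(tt$pheno, tt$design, plan, learner = perfect)
  m2 <- run_dl_m2(tt$pheno, tt$design, plan, learner = perfect)
  expect_true(all(m2$final_train_sizes < m1$final_train_sizes))
  expect_true(all(m2$final_train_sizes ==
                    lengths(purrr::map(plan$splits, "inner_train"))))
  expect_error(run_dl_m2(tt$pheno, tt$design,
                         make_split_plan(tt$pheno, 5, 1), learner = perfect),
               "nested")
})

test_that("constant validation predictions fall back to the identity line with a warning", {
  tt <- tiny_trial(n_lines = 20, n_markers = 40, n_env = 2, seed = 44,
                   include_ge = FALSE)
  plan <- make_split_plan(tt$pheno, k = 4, seed = 11, nested = TRUE)
  constant <- oracle_learner(record_values(rep(1, nrow(tt$pheno))))
  warnings <- capture_warnings(
    res <- run_dl_m2(tt$pheno, tt$design, plan, learner = constant))
  expect_equal(length(warnings), plan$k) # one fallback per fold
  expect_true(all(grepl("identity", warnings)))
  expect_true(all(purrr::map_dbl(res$calibration, "slope") == 1))
})

test_that("GBLUP cross-validation beats the mean predictor on heritable traits and is deterministic", {
  tt <- tiny_trial(n_lines = 200, n_markers = 200, n_env = 2, seed = 45,
                   h2 = 0.8, ge_ratio = 0, include_ge = FALSE)
  plan <- make_split_plan(tt$pheno, k = 5, seed = 12)
  res <- run_gblup_cv(tt$pheno, tt$design, plan)
  expect_lt(mean(res$fold_mse$mse), var(tt$pheno$value))
  expect_identical(sort(res$predictions$record), seq_len(nrow(tt$pheno)))
  res2 <- run_gblup_cv(tt$pheno, tt$design, plan)
  expect_identical(res$fold_mse, res2$fold_mse)
})

test_that("protocols with a real network run end to end on a reduced grid", {
  tt <- tiny_trial(n_lines = 12, n_markers = 30, n_env = 2, seed = 46,
                   include_ge = FALSE)
  plan <- make_split_plan(tt$pheno, k = 3, seed = 13, nested = TRUE)
  small_grid <- tibble::tibble(units_multiplier = 1.5, n_hidden_layers = 1L,
                               dropout = 0.15, learning_rate = 0.001,
                               epochs = 20L)
  m1 <- run_dl_m1(tt$pheno, tt$design, plan, learner = mlp_learner(),
                  grid = small_grid)
  m2 <- run_dl_m2(tt$pheno, tt$design, plan, learner = mlp_learner(),
                  grid = small_grid)
  expect_identical(sort(m1$predictions$record), seq_len(24L))
  expect_identical(sort(m2$predictions$record), seq_len(24L))
  expect_true(all(is.finite(m2$predictions$predicted)))
})
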