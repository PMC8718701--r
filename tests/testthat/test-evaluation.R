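# construct a protocol_result by hand so report-level behaviour can be
# tested on exactly controlled predictions
fake_result <- function(method, preds, include_ge = FALSE,
                        plan = list(k = 2L, seed = 1L, n = nrow(preds))) {
  gpcalib:::new_protocol_result(method, include_ge, preds,
                                structure(plan, class = "split_plan"))
}

test_that("mse is the mean squared difference and scales quadratically", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  o <- rnorm(10); p <- rnorm(10)
  expect_equal(mse(3 * o, 3 * p), 9 * mse(o, p))
  expect_error(mse(1:3, 1:2), "equal length")
})

test_that("percent MSE change follows the baseline-in-denominator convention", {
  expect_equal(percent_mse_change(2, 2), 0)
  expect_equal(percent_mse_change(2, 1), 50)
  expect_lt(percent_mse_change(1, 2), 0) # method worse than baseline
  expect_error(percent_mse_change(0, 1), "positive")
  # antisymmetry under swapping after the sign transform
  a <- percent_mse_change(2.5, 1.75)
  swapped <- percent_mse_change(1.75, 2.5)
  expect_equal(swapped, 100 * (1 - (1 - a / 100)^-1))
})

test_that("reports average fold MSEs (not pooled records) and are reproducible", {
  # unequal per-env fold sizes make the two averaging orders differ
  preds <- tibble::tibble(
    record = 1:6, fold = c(1L, 1L, 1L, 2L, 2L, 2L),
    line_id = "x", env_id = c("E1", "E1", "E2", "E1", "E2", "E2"),
    observed = c(0, 0, 0, 0, 0, 0),
    predicted = c(1, 1, 3, 2, 1, 1))
  res <- fake_result("m", preds)
  rep <- build_report(list(res))
  e1 <- rep$cells[rep$cells$env_id == "E1", ]
  # fold MSEs for E1: fold1 = 1, fold2 = 4 -> mean 2.5; pooled would be 2
  expect_equal(e1$mse, 2.5)
  pooled <- mse(preds$observed[preds$env_id == "E1"],
                preds$predicted[preds$env_id == "E1"])
  expect_false(isTRUE(all.equal(e1$mse, pooled)))
  expect_equal(e1$se, sd(c(1, 4)) / sqrt(2))
  # pure function of its inputs
  expect_equal(build_report(list(res))$cells, rep$cells)
})

test_that("report cells cover methods x environments x interaction settings", {
  mk <- function(method, ge, shift) {
    preds <- tidyr::expand_grid(fold = 1:2, env_id = c("E1", "E2", "E3"),
                                rep = 1:2) |>
      dplyr::mutate(record = dplyr::row_number(), line_id = "x",
                    observed = 0, predicted = shift) |>
      dplyr::select(record, fold, line_id, env_id, observed, predicted)
    fake_result(method, preds, include_ge = ge,
                plan = list(k = 2L, seed = 1L, n = 12L))
  }
  rep <- build_report(list(mk("a", FALSE, 1), mk("b", FALSE, 2),
                           mk("a", TRUE, 1), mk("b", TRUE, 2)))
  expect_equal(nrow(rep$cells), 2 * 2 * 4) # 2 methods x 2 settings x (3 env + across)
  expect_setequal(unique(rep$cells$env_id), c("E1", "E2", "E3", "across"))
  # a perfect predictor scores zero in every cell
  perfect <- build_report(list(mk("p", FALSE, 0)))
  expect_true(all(perfect$cells$mse == 0))
  # percent-change table carries both raw MSEs for every ordered pair
  pc <- rep$percent_change
  expect_true(all(c("mse_baseline", "mse_method", "pct_change") %in% names(pc)))
  row <- pc[pc$baseline == "b" & pc$method == "a" & pc$env_id == "across" &
              pc$ge == "NO GE", ]
  expect_equal(row$pct_change, 100 * (4 - 1) / 4)
})

test_that("results from different split plans cannot be mixed", {
  preds <- tibble::tibble(record = 1:2, fold = c(1L, 2L), line_id = "x",
                          env_id = "E1", observed = 0, predicted = 1)
  r1 <- fake_result("a", preds, plan = list(k = 2L, seed = 1L, n = 2L))
  r2 <- fake_result("b", preds, plan = list(k = 2L, seed = 2L, n = 2L))
  expect_error(build_report(list(r1, r2)), "same split plan")
})

test_that("tidiers and plots expose the result surfaces", {
  preds <- tibble::tibble(record = 1:4, fold = c(1L, 1L, 2L, 2L),
                          line_id = "x", env_id = c("E1", "E2", "E1", "E2"),
                          observed = c(0, 0, 0, 0), predicted = c(1, 2, 1, 2))
  res <- fake_result("m", preds)
  td <- tidy(res)
  expect_setequal(names(td), c("method", "ge", "fold", "env_id", "mse"))
  expect_equal(nrow(glance(res)), 1L)
  rep <- build_report(list(res))
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(autoplot(res), "ggplot")
  expect_identical(tidy(rep), rep$cells)
})
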