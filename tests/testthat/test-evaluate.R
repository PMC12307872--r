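# Error metrics, stratification, paired tests and cross-validation wiring.

test_that("error metrics match their worked examples and scale properties", {
  expect_equal(mape_percent(c(100, 200), c(90, 220)), 10.0)
  expect_equal(mape_percent(c(100, 200), c(100, 200)), 0)
  expect_equal(mape_percent(50, 100), 100.0)
  expect_equal(mean_absolute_point_error(c(100, 200), c(90, 220)), 15)
  expect_equal(mean_absolute_point_error(c(5, 5), c(5, 5)), 0)
  expect_equal(mean_absolute_point_error(c(100, 100), c(110, 90)), 10)
  set.seed(3)
  a <- runif(50, 60, 300); p <- a + rnorm(50, 0, 20)
  expect_equal(mape_percent(3 * a, 3 * p), mape_percent(a, p))
  expect_equal(mean_absolute_point_error(3 * a, 3 * p),
               3 * mean_absolute_point_error(a, p))
  expect_error(mape_percent(c(0, 100), c(1, 1)), "positive")
  expect_error(mean_absolute_point_error(numeric(0), numeric(0)), "non-empty")
})

test_that("stratification uses actual values and reports undefined strata as NA", {
  s <- stratified_metrics(c(60, 100, 200), c(66, 110, 180))
  expect_identical(s$n, c(3L, 1L, 1L))
  expect_equal(s$mae_mgdl[s$stratum == "hypoglycaemic"], 6)
  expect_equal(s$mae_mgdl[s$stratum == "hyperglycaemic"], 20)
  s2 <- stratified_metrics(c(100, 150), c(90, 160))
  expect_true(all(is.na(s2$mape_pct[2:3])))
  expect_identical(s2$n[2:3], c(0L, 0L))
})

test_that("paired t-test matches an analytic oracle and degenerate rules", {
  r <- paired_t_test(c(1, 0), c(0, 1))       # differences 1, -1
  expect_equal(r$t, 0); expect_equal(r$p, 1); expect_identical(r$stars, "")
  r0 <- paired_t_test(c(2, 3, 4), c(2, 3, 4))
  expect_equal(r0$p, 1); expect_true(r0$degenerate)
  rc <- paired_t_test(c(2, 3, 4), c(1, 2, 3))  # constant nonzero differences
  expect_equal(rc$p, 0); expect_true(rc$degenerate)
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    got <- paired_t_test(a, b)
    ref <- t.test(a, b, paired = TRUE)        # independent route via t.test
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(paired_t_test(1, 1), "2 points")
})

test_that("null calibration: identically distributed errors rarely reach significance", {
  set.seed(99)
  rejections <- replicate(200, {
    truth <- runif(40, 80, 250)
    err_a <- abs(truth - (truth + rnorm(40, 0, 15)))
    err_b <- abs(truth - (truth + rnorm(40, 0, 15)))
    paired_t_test(err_a, err_b)$p < 0.05
  })
  rate <- mean(rejections)
  expect_gte(rate, 0.01); expect_lte(rate, 0.12)
})

test_that("cross-validation partitions predictions and excludes the held-out day", {
  co <- tiny_cohort(n_patients = 2, n_sensor1 = 0, days = 3, seed = 51)
  ds <- thin_windows(prepare_windows(co$series, 30), 4)
  cv <- cv_glucast(ds, control = tiny_config(epochs = 2, seed = 1))
  expect_length(cv$folds, 3)
  expect_identical(nrow(cv$pooled), n_windows(ds))
  folds <- leave_one_day_out_folds(ds)
  for (k in seq_along(folds))
    expect_false(any(ds$day[folds[[k]]$train] == folds[[k]]$day))
  # pooled MAE equals the window-count-weighted mean of per-fold MAEs
  per_fold <- vapply(cv$folds, function(f)
    mean_absolute_point_error(f$actual, f$predicted), 0)
  wts <- vapply(cv$folds, function(f) length(f$actual), 0)
  expect_equal(mean_absolute_point_error(cv$pooled$actual, cv$pooled$predicted),
               sum(per_fold * wts) / sum(wts), tolerance = 1e-9)
  # predictions finite and in a plausible glucose range
  expect_true(all(is.finite(cv$pooled$predicted)))
})

test_that("persistence baseline repeats the last observed input", {
  s <- series_5min(seq(100, 190, by = 5))
  ds <- make_windows(s, 15)
  expect_equal(persistence_forecast(ds), ds$inputs[, 6])
  expect_equal(ds$targets - persistence_forecast(ds),
               rep(15, n_windows(ds)))   # ramp of 5 mg/dL per step, h = 3
})
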