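# Loading, exclusion rule, grid resampling, imputation, scaling, ADF check.

test_that("CSV round trip preserves the cohort and collapses duplicates", {
  co <- tiny_cohort()
  dir <- file.path(tempdir(), "roundtrip")
  write_cohort(co, dir)
  series <- load_cgm_csv(file.path(dir, "cgm.csv"))
  expect_length(series, 3)
  s0 <- co$series[[1]]
  s1 <- series[[s0$patient_id]]
  expect_equal(s1$glucose, s0$glucose)
  expect_equal(as.numeric(s1$time), as.numeric(s0$time))
  expect_equal(s1$native_interval, s0$native_interval)
  bl <- load_baseline_csv(file.path(dir, "baseline.csv"))
  expect_equal(bl[["HbA1c (%)"]], co$baseline[["HbA1c (%)"]], tolerance = 1e-8)

  # duplicated timestamp collapses to the mean
  f <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,timestamp,glucose_mgdl,sensor",
               "A,2023-03-01T00:00:00Z,100,sensor2",
               "A,2023-03-01T00:00:00Z,110,sensor2",
               "A,2023-03-01T00:15:00Z,120,sensor2",
               "A,2023-03-01T00:30:00Z,130,sensor2"), f)
  s <- load_cgm_csv(f)[["A"]]
  expect_equal(s$glucose, c(105, 120, 130))

  # empty file: empty list with a warning
  f2 <- tempfile(fileext = ".csv")
  writeLines("patient_id,timestamp,glucose_mgdl,sensor", f2)
  expect_warning(out <- load_cgm_csv(f2), "empty")
  expect_length(out, 0)

  # missing column rejected
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,timestamp,sensor", "A,2023-03-01T00:00:00Z,s"), f3)
  expect_error(load_cgm_csv(f3), "glucose_mgdl")
})

test_that("exclusion is strict at 50% missing", {
  v <- rep(100, 100)
  s <- series_5min(v)
  expect_equal(missing_fraction(s), 0)
  expect_false(is_excluded(s))
  v[1:50] <- NA                     # exactly 50%
  s50 <- series_5min(v)
  expect_equal(missing_fraction(s50), 0.5)
  expect_false(is_excluded(s50))    # strict "more than 50%"
  v[1:60] <- NA                     # 60%
  expect_true(is_excluded(series_5min(v)))
  # monotone: observing more samples never flips retained -> excluded
  fr <- sapply(0:99, function(k) {
    vv <- rep(NA_real_, 100); if (k > 0) vv[seq_len(k)] <- 100
    missing_fraction(series_5min(vv))
  })
  expect_true(all(diff(fr) <= 0))
})

test_that("15-min upsampling is linear and exact on affine signals", {
  tm <- as.POSIXct("2023-03-01 00:00:00", tz = "UTC") + (0:9) * 900
  s <- cgm_series("P", tm, 100 + 2.4 * (0:9), native_interval = 15)
  r <- resample_to_grid(s)
  expect_equal(r$native_interval, 5)
  expect_equal(diff(as.numeric(r$time)), rep(300, length(r$time) - 1))
  expect_lt(max(abs(r$glucose - (100 + 2.4 * seq(0, 9, by = 1 / 3)))), 1e-9)
  # worked example: [100, 130] -> [100, 110, 120, 130]
  s2 <- cgm_series("P", tm[1:2], c(100, 130), native_interval = 15)
  expect_equal(resample_to_grid(s2)$glucose, c(100, 110, 120, 130))
})

test_that("upsampling does not bridge native gaps", {
  tm <- as.POSIXct("2023-03-01 00:00:00", tz = "UTC") + (0:4) * 900
  s <- cgm_series("P", tm, c(100, NA, 130, 145, 160), native_interval = 15)
  r <- resample_to_grid(s)
  # grid points inside the [0,30] min stretch around the missing native sample
  # stay missing; the observed segment is interpolated
  expect_true(is.na(r$glucose[2]) && is.na(r$glucose[3]))  # 5, 10 min
  expect_true(all(!is.na(r$glucose[7:13])))
  expect_equal(r$glucose[7:9], c(130, 135, 140))
})

test_that("1-min downsampling averages non-overlapping 5-min bins", {
  tm <- as.POSIXct("2023-03-01 00:00:00", tz = "UTC") + (0:14) * 60
  s <- cgm_series("P", tm, 0:14 + 100, native_interval = 1)
  r <- resample_to_grid(s)
  expect_equal(r$glucose, c(2, 7, 12) + 100)
  expect_equal(as.numeric(diff(r$time)), c(5, 5))
  # decimation option takes bin starts
  expect_equal(resample_to_grid(s, downsample = "decimate")$glucose,
               c(0, 5, 10) + 100)
  # constant stays constant at any interval
  sc <- cgm_series("P", tm, rep(100, 15), native_interval = 1)
  expect_equal(resample_to_grid(sc)$glucose, rep(100, 3))
})

test_that("interior gaps are interpolated, edges dropped, gaps recorded", {
  s <- series_5min(c(100, NA, 120))
  r <- interpolate_missing(s)
  expect_equal(r$glucose, c(100, 110, 120))
  expect_equal(attr(r, "imputed"), c(FALSE, TRUE, FALSE))
  g <- attr(r, "gaps")
  expect_identical(g$n_samples, 1L)
  expect_equal(g$minutes, 5)

  s2 <- series_5min(c(NA, 100, 110))
  r2 <- interpolate_missing(s2)
  expect_equal(r2$glucose, c(100, 110))
  expect_equal(r2$time, s2$time[2:3])

  s3 <- series_5min(c(100, 105, 120))
  expect_identical(interpolate_missing(s3)$glucose, s3$glucose)
  expect_error(interpolate_missing(series_5min(c(NA_real_, NA_real_))),
               "all-missing")
})

test_that("min-max scaling round-trips and handles the degenerate case", {
  s <- fit_minmax(c(70, 180))
  expect_equal(apply_minmax(125, s), 0.5)
  set.seed(1)
  x <- runif(1000, -50, 500)
  expect_lt(max(abs(invert_minmax(apply_minmax(x, s), s) - x)), 1e-9)
  # training data maps into [0,1]; outside values extrapolate, unclipped
  expect_true(apply_minmax(200, s) > 1)
  expect_warning(sd0 <- fit_minmax(rep(5, 3)), "degenerate")
  expect_equal(apply_minmax(c(1, 5, 9), sd0), c(0, 0, 0))
})

test_that("ADF check separates stationary AR(1) from a random walk", {
  rejections <- function(gen) {
    mean(sapply(1:100, function(s) {
      set.seed(s)
      adf_check(gen(), max_lag = 2)$reject_unit_root
    }))
  }
  ar1 <- function() as.numeric(arima.sim(list(ar = 0.5), 500))
  rw <- function() cumsum(rnorm(500))
  expect_gte(rejections(ar1), 0.90)
  expect_lte(rejections(rw), 0.20)
  # too-short series: flagged, not an error
  expect_warning(out <- adf_check(rnorm(30)), "50")
  expect_true(is.na(out$statistic) && out$flagged)
  # deterministic linear trend: no numerical failure
  expect_no_error(adf_check(seq(0, 100, length.out = 200)))
})
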