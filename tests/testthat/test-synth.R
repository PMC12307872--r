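# Synthetic cohort generator: distributional recovery, determinism, and the
# baseline-to-dynamics effect channel.

test_that("baseline records recover the cohort summary statistics", {
  set.seed(123)
  tab <- do.call(rbind, replicate(1, glucast:::.simulate_baseline_table(10000),
                                  simplify = FALSE))
  expect_lt(abs(mean(tab[["HbA1c (%)"]]) - 7.42), 0.1)
  expect_lt(abs(sd(tab[["HbA1c (%)"]]) - 1.11), 0.2)
  expect_lt(abs(mean(tab$Age) - 67) / 67, 0.02)
  expect_lt(abs(mean(tab[["Weight (kg)"]]) - 80.42) / 80.42, 0.02)
  expect_lt(abs(mean(tab$Gender) - 0.55), 0.03)
  # nonnegative throughout
  expect_true(all(as.matrix(tab) >= 0))
})

test_that("baseline draws are reproducible and unaffected by effect_scale", {
  set.seed(7); r1 <- simulate_baseline_record(effect_scale = 0)
  set.seed(7); r2 <- simulate_baseline_record(effect_scale = 5)
  expect_identical(r1, r2)
})

test_that("glucose trace follows the deterministic skeleton when noise is off", {
  pr <- structure(list(patient_id = "P1", basal = 28.7 * 7 - 46.7,
                       circadian_amplitude = 0, circadian_phase = 0,
                       meal_amplitudes = c(0, 0, 0), ar_coef = 0.9,
                       innovation_sd = 0), class = "patient_profile")
  tr <- simulate_glucose_trace(pr, duration_days = 1, sampling_interval = 5)
  expect_equal(unique(tr$glucose), 154.2, tolerance = 1e-12)
  expect_length(tr$glucose, 288)
})

test_that("trace length matches duration and interval", {
  pr <- patient_profile(data.frame(`HbA1c (%)` = 7, check.names = FALSE))
  expect_length(simulate_glucose_trace(pr, 10, 5)$glucose, 2880)
  expect_length(simulate_glucose_trace(pr, 1, 15)$glucose, 96)
  expect_error(simulate_glucose_trace(pr, 1, 7), "1, 5 or 15")
})

test_that("higher HbA1c raises the mean trace level monotonically", {
  means <- sapply(c(6, 7, 8, 9), function(h) {
    mean(sapply(1:20, function(s) {
      set.seed(s)
      pr <- patient_profile(data.frame(`HbA1c (%)` = h, check.names = FALSE))
      mean(simulate_glucose_trace(pr, 1, 15)$glucose)
    }))
  })
  expect_true(all(diff(means) > 0))
})

test_that("missingness injection hits the target fraction with contiguous gaps", {
  pr <- patient_profile(data.frame(`HbA1c (%)` = 7.4, check.names = FALSE))
  set.seed(11)
  tr <- simulate_glucose_trace(pr, 10, 5)
  expect_identical(inject_missingness(tr, 0), tr)
  set.seed(12)
  out <- inject_missingness(tr, 0.3)
  frac <- mean(is.na(out$glucose))
  expect_gte(frac, 0.28); expect_lte(frac, 0.32)
  expect_identical(out$time, tr$time)
  # mostly contiguous: mean gap run length well above 1
  r <- rle(is.na(out$glucose))
  expect_gt(mean(r$lengths[r$values]), 2)
  # determinism
  set.seed(12)
  out2 <- inject_missingness(tr, 0.3)
  expect_identical(out, out2)
  expect_error(inject_missingness(tr, 1), "\\[0, 1\\)")
})

test_that("cohort composition follows the configuration", {
  co <- simulate_cohort(cohort_config(n_patients = 6, n_sensor1 = 2,
                                      duration_days = c(2, 4), seed = 3))
  sensors <- vapply(co$series, `[[`, "", "sensor")
  expect_length(co$series, 6)
  expect_identical(sum(sensors == "sensor1"), 2L)
  expect_identical(sum(sensors == "sensor2"), 4L)
  ivals <- vapply(co$series, `[[`, 0, "native_interval")
  expect_true(all(ivals[sensors == "sensor1"] == 1))
  expect_true(all(ivals[sensors == "sensor2"] == 15))
  expect_identical(nrow(co$truth), 6L)
  expect_identical(nrow(co$baseline), 6L)
  # durations within range
  expect_true(all(co$truth$duration_days >= 2 & co$truth$duration_days <= 4))
})

test_that("identical config and seed give identical cohorts, including CSV bytes", {
  cfg <- cohort_config(n_patients = 2, n_sensor1 = 1, duration_days = c(2, 2),
                       seed = 42)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in c("cgm.csv", "baseline.csv", "truth.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("effect channel: trace level tracks HbA1c only when the scale is on", {
  level_cor <- function(scale) {
    co <- simulate_cohort(cohort_config(n_patients = 200, n_sensor1 = 0,
                                        duration_days = c(2, 2),
                                        missing_fraction = 0,
                                        baseline_effect_scale = scale,
                                        seed = 27))
    m <- vapply(co$series, function(s) mean(s$glucose), 0)
    cor(m, co$baseline[["HbA1c (%)"]])
  }
  expect_lt(abs(level_cor(0)), 0.1)
  expect_gt(level_cor(1), 0.8)
})

test_that("table5 attrition masks variables with non-increasing availability", {
  co <- simulate_cohort(cohort_config(n_patients = 40, n_sensor1 = 15,
                                      duration_days = c(2, 2),
                                      table5_attrition = TRUE, seed = 9))
  counts <- sapply(0:6, function(s) {
    vars <- variable_set_names(s)
    sum(stats::complete.cases(co$baseline[, vars, drop = FALSE]))
  })
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[1], 40L)        # everyone holds set 0
})
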