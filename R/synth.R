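# Synthetic type 2 diabetes cohort simulator.
#
# Emulates the structure of a two-sensor CGM pilot study: baseline
# health-record covariates drawn from published cohort summary statistics,
# per-patient glucose dynamics (basal level tied to HbA1c, circadian rhythm,
# meal excursions, AR(1) sensor noise) and contiguous sensor-dropout gaps.

# Baseline covariate summary statistics (mean, sd) of the emulated cohort.
# Gender is Bernoulli (1 = female) and handled separately.
.baseline_vars <- function() {
  v <- rbind(
    c("Age",                               67,     9),
    c("Weight (kg)",                       80.42,  28.46),
    c("Height (m)",                        1.63,   0.12),
    c("Waist circumference (cm)",          104.13, 16.5),
    c("Blood Glucose (mg/dL)",             136.6,  45.19),
    c("HbA1c (%)",                         7.42,   1.11),
    c("Creatinine (mg/dL)",                1.99,   1.52),
    c("Urea level (mg/dL)",                49.44,  30.65),
    c("Total cholesterol (mg/dL)",         144.82, 33.78),
    c("LDL cholesterol (mg/dL)",           67.17,  32.11),
    c("HDL cholesterol (mg/dL)",           46.86,  10.83),
    c("Triglycerides (mg/dL)",             203.71, 247.43),
    c("White blood cell count (10^3/uL)",  7.29,   1.83),
    c("Red blood cell count (10^3/uL)",    25.26,  37.27),
    c("Haematocrit (%)",                   39.76,  8.86),
    c("Plt (x1000/uL)",                    206.31, 80.53),
    c("SGOT (IU/L)",                       35.42,  32.22),
    c("SGPT (IU/L)",                       25.99,  14.12),
    c("K (mmol/L)",                        4.57,   0.48),
    c("Na (mmol/L)",                       125.52, 42.24)
  )
  data.frame(name = v[, 1], mean = as.numeric(v[, 2]), sd = as.numeric(v[, 3]),
             stringsAsFactors = FALSE)
}

# Nested baseline variable sets (availability sets 0-6). Each set extends the
# previous one; the per-sensor patient counts mirror the emulated study's
# availability attrition.
.variable_sets <- list(
  `0` = c("Age", "Gender"),
  `1` = c("Age", "Gender", "HbA1c (%)"),
  `2` = c("Age", "Gender", "HbA1c (%)", "Weight (kg)", "Height (m)"),
  `3` = c("Age", "Gender", "HbA1c (%)", "Weight (kg)", "Height (m)",
          "HDL cholesterol (mg/dL)", "Total cholesterol (mg/dL)"),
  `4` = c("Age", "Gender", "HbA1c (%)", "Weight (kg)", "Height (m)",
          "HDL cholesterol (mg/dL)", "Total cholesterol (mg/dL)",
          "Blood Glucose (mg/dL)", "Urea level (mg/dL)"),
  `5` = c("Age", "Gender", "HbA1c (%)", "Weight (kg)", "Height (m)",
          "HDL cholesterol (mg/dL)", "Total cholesterol (mg/dL)",
          "Blood Glucose (mg/dL)", "Urea level (mg/dL)",
          "K (mmol/L)", "Haematocrit (%)", "LDL cholesterol (mg/dL)"),
  `6` = c("Age", "Gender", "HbA1c (%)", "Weight (kg)", "Height (m)",
          "HDL cholesterol (mg/dL)", "Total cholesterol (mg/dL)",
          "Blood Glucose (mg/dL)", "Urea level (mg/dL)",
          "K (mmol/L)", "Haematocrit (%)", "LDL cholesterol (mg/dL)",
          "SGOT (IU/L)", "White blood cell count (10^3/uL)")
)

# Patients with at least variable set j, per sensor, in the emulated study.
.attrition_counts <- list(sensor1 = c(15, 8, 6, 5, 5, 3, 2),
                          sensor2 = c(25, 17, 13, 9, 7, 5, 4))

#' Baseline variable sets
#'
#' Returns the ordered column names of one of the nested baseline variable
#' availability sets (0--6). Set 0 is `Age`, `Gender`; each later set adds
#' further biochemical/anthropometric variables, mirroring the attrition of
#' health-record availability in the emulated study.
#'
#' @param set integer in 0..6.
#' @return character vector of baseline column names.
#' @export
#' @examples
#' variable_set_names(0)
#' variable_set_names(2)
variable_set_names <- function(set) {
  .assert(length(set) == 1 && set %in% 0:6, "variable set must be one of 0..6")
  .variable_sets[[as.character(set)]]
}

#' Synthetic cohort configuration
#'
#' Configuration for [simulate_cohort()]. Defaults emulate the study cohort:
#' 40 patients, 15 on a 1-min-sampled sensor ("sensor1") and 25 on a
#' 15-min-sampled sensor ("sensor2"), monitored for 8--28 days.
#'
#' @param n_patients number of patients.
#' @param n_sensor1 how many of them wear the 1-min sensor (the rest wear the
#'   15-min sensor).
#' @param duration_days length-2 integer range of per-patient monitoring
#'   duration in days (inclusive).
#' @param missing_fraction target fraction of samples lost to contiguous
#'   sensor-dropout gaps, in `[0, 0.9]`.
#' @param baseline_effect_scale nonnegative multiplier on the influence of
#'   baseline covariates (HbA1c) on the glucose dynamics; 0 disconnects the
#'   baseline record from the trace.
#' @param sensor1_interval,sensor2_interval native sampling intervals
#'   (minutes) of the two sensor types; each must be 1, 5 or 15.
#' @param table5_attrition if `TRUE`, mask baseline variables per patient so
#'   the per-sensor counts of patients holding each variable set reproduce the
#'   emulated study's availability attrition.
#' @param seed integer seed; the same config + seed yields a bit-identical
#'   cohort.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 40L, n_sensor1 = 15L,
                          duration_days = c(8L, 28L),
                          missing_fraction = 0.05,
                          baseline_effect_scale = 1,
                          sensor1_interval = 1L, sensor2_interval = 15L,
                          table5_attrition = FALSE, seed = 1L) {
  .assert(n_patients >= 1, "n_patients must be positive")
  .assert(n_sensor1 >= 0 && n_sensor1 <= n_patients,
          "n_sensor1 must lie in [0, n_patients]")
  .assert(length(duration_days) %in% c(1L, 2L) && all(duration_days >= 1),
          "duration_days must be a positive integer or range")
  if (length(duration_days) == 1L) duration_days <- rep(duration_days, 2L)
  .assert(duration_days[1] <= duration_days[2], "invalid duration range")
  .assert(missing_fraction >= 0 && missing_fraction <= 0.9,
          "missing_fraction must lie in [0, 0.9]")
  .assert(baseline_effect_scale >= 0, "baseline_effect_scale must be >= 0")
  .assert(sensor1_interval %in% c(1, 5, 15) && sensor2_interval %in% c(1, 5, 15),
          "sampling intervals must be 1, 5 or 15 minutes")
  structure(list(n_patients = as.integer(n_patients),
                 n_sensor1 = as.integer(n_sensor1),
                 duration_days = as.integer(duration_days),
                 missing_fraction = missing_fraction,
                 baseline_effect_scale = baseline_effect_scale,
                 sensor1_interval = as.integer(sensor1_interval),
                 sensor2_interval = as.integer(sensor2_interval),
                 table5_attrition = isTRUE(table5_attrition),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# truncated normal via rejection; truncation bounds are wide (see docs) so
# acceptance probability is ~1
.rtnorm <- function(n, mean, sd, lower, upper) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

.simulate_baseline_table <- function(n) {
  vars <- .baseline_vars()
  out <- data.frame(Gender = rbinom(n, 1L, 0.55), check.names = FALSE)
  for (i in seq_len(nrow(vars))) {
    m <- vars$mean[i]; s <- vars$sd[i]
    # near-symmetric [mu - 4 sd, mu + 4 sd] window clipped at zero: keeps the
    # values physiologically nonnegative without biasing the recovered mean
    out[[vars$name[i]]] <- .rtnorm(n, m, s, max(0, m - 4 * s), m + 4 * s)
  }
  out[, c("Age", "Gender", setdiff(names(out), c("Age", "Gender")))]
}

#' Simulate one baseline health record
#'
#' Draws a single patient's baseline record from truncated normal
#' distributions matching the emulated cohort's published means and standard
#' deviations (e.g. age 67 +/- 9 years, HbA1c 7.42 +/- 1.11 %, weight
#' 80.42 +/- 28.46 kg); `Gender` is Bernoulli with probability 0.55 of being
#' female (coded 1). Draws come from the current R random number stream; call
#' `set.seed()` beforehand for reproducibility.
#'
#' @param effect_scale carried along for interface symmetry with the dynamics
#'   simulator; it does not affect the distribution of the record.
#' @return one-row `data.frame` with all baseline variables.
#' @export
#' @examples
#' set.seed(1)
#' simulate_baseline_record()
simulate_baseline_record <- function(effect_scale = 1) {
  .assert(effect_scale >= 0, "effect_scale must be >= 0")
  .simulate_baseline_table(1L)
}

# mean CGM glucose implied by HbA1c (standard eAG mapping)
.eag <- function(hba1c) 28.7 * hba1c - 46.7

#' Latent dynamics parameters for one synthetic patient
#'
#' Derives the glucose-dynamics parameters from a baseline record. The basal
#' level is the estimated average glucose implied by HbA1c, attenuated towards
#' the cohort-typical level by `effect_scale` (0 = no baseline influence) and
#' clamped to `[70, 300]` mg/dL. Circadian amplitude, meal amplitudes and the
#' AR(1) innovation SD are drawn from the current RNG stream.
#'
#' @param baseline one-row baseline record (needs `HbA1c (%)`).
#' @param effect_scale nonnegative multiplier of the HbA1c effect.
#' @param patient_id id stored with the profile.
#' @return list of latent parameters (class `patient_profile`).
#' @export
patient_profile <- function(baseline, effect_scale = 1, patient_id = "P1") {
  hba1c <- baseline[["HbA1c (%)"]]
  .assert(is.finite(hba1c), "baseline record must contain a finite HbA1c (%)")
  basal <- .eag(7.42) + effect_scale * (.eag(hba1c) - .eag(7.42))
  basal <- min(300, max(70, basal))
  structure(list(patient_id = patient_id,
                 basal = basal,
                 circadian_amplitude = runif(1, 10, 30),
                 circadian_phase = runif(1, -pi, pi),
                 meal_amplitudes = runif(3, 30, 80),
                 ar_coef = 0.9,          # at 5-min steps
                 innovation_sd = runif(1, 2, 8)),
            class = "patient_profile")
}

#' Simulate a CGM glucose trace
#'
#' Generates `duration_days` of interstitial glucose at a fixed sampling
#' interval:
#' `g(t) = basal + A sin(2 pi t / 24h + phi) + sum_k M_k k(t - t_k) + e(t)`,
#' clamped to the common CGM reporting range `[40, 400]` mg/dL. Meals occur
#' around 08:00, 13:00 and 20:00 (jittered +/- 45 min each day) with response
#' kernel `k(u) = (u/tau) exp(1 - u/tau)`, `tau` = 60 min. `e(t)` is an AR(1)
#' process on the sampling grid; its coefficient is 0.9 at 5-min spacing and
#' is rescaled for other intervals so the stationary noise level is
#' interval-independent.
#'
#' @param profile a [patient_profile()].
#' @param duration_days integer >= 1.
#' @param sampling_interval minutes between samples; one of 1, 5, 15.
#' @param start first timestamp (POSIXct, UTC midnight by default).
#' @param sensor sensor label stored on the series.
#' @return a [cgm_series()].
#' @export
#' @examples
#' set.seed(1)
#' pr <- patient_profile(simulate_baseline_record())
#' tr <- simulate_glucose_trace(pr, duration_days = 2, sampling_interval = 5)
#' length(tr$glucose)  # 2 * 288
simulate_glucose_trace <- function(profile, duration_days, sampling_interval,
                                   start = as.POSIXct("2023-03-01 00:00:00",
                                                      tz = "UTC"),
                                   sensor = "sensor2") {
  .assert(sampling_interval %in% c(1, 5, 15),
          "sampling_interval must be 1, 5 or 15 minutes")
  .assert(duration_days >= 1, "duration_days must be >= 1")
  n <- as.integer(duration_days * 24 * 60 / sampling_interval)
  tmin <- (seq_len(n) - 1) * sampling_interval      # minutes since start
  g <- profile$basal +
    profile$circadian_amplitude *
      sin(2 * pi * tmin / (24 * 60) + profile$circadian_phase)
  meal_clock <- c(8, 13, 20) * 60
  tau <- 60
  for (d in seq_len(duration_days) - 1L) {
    for (k in 1:3) {
      t_meal <- d * 1440 + meal_clock[k] + runif(1, -45, 45)
      u <- tmin - t_meal
      idx <- which(u >= 0 & u < 6 * tau)
      if (length(idx))
        g[idx] <- g[idx] +
          profile$meal_amplitudes[k] * (u[idx] / tau) * exp(1 - u[idx] / tau)
    }
  }
  phi <- profile$ar_coef ^ (sampling_interval / 5)
  sd_stat <- profile$innovation_sd / sqrt(1 - profile$ar_coef ^ 2)
  if (sd_stat > 0) {
    innov <- rnorm(n, 0, sd_stat * sqrt(1 - phi ^ 2))
    e0 <- rnorm(1, 0, sd_stat)
    noise <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                      init = e0))
    g <- g + noise
  }
  g <- pmin(400, pmax(40, g))
  cgm_series(patient_id = profile$patient_id,
             time = start + tmin * 60,
             glucose = g, sensor = sensor,
             native_interval = sampling_interval)
}

#' Inject contiguous sensor-dropout gaps
#'
#' Replaces glucose values with the missing marker (`NA`) in contiguous gap
#' segments with geometric lengths (mean 6 samples) until the realised missing
#' fraction equals the target (to within one sample, hence well inside the
#' +/- 2 percentage point band). Timestamps are untouched.
#'
#' @param series a [cgm_series()].
#' @param missing_fraction target fraction in `[0, 1)`.
#' @return the series with gaps injected.
#' @export
inject_missingness <- function(series, missing_fraction) {
  .assert(inherits(series, "cgm_series"), "series must be a cgm_series")
  .assert(missing_fraction >= 0 && missing_fraction < 1,
          "missing_fraction must lie in [0, 1)")
  L <- length(series$glucose)
  target <- round(missing_fraction * L)
  if (target == 0) return(series)
  miss <- logical(L)
  while (sum(miss) < target) {
    s <- sample.int(L, 1L)
    len <- rgeom(1, 1 / 6) + 1L
    seg <- s:min(L, s + len - 1L)
    newly <- seg[!miss[seg]]
    need <- target - sum(miss)
    if (length(newly) > need) newly <- newly[seq_len(need)]
    miss[newly] <- TRUE
  }
  series$glucose[miss] <- NA_real_
  series
}

#' Simulate a full synthetic cohort
#'
#' Draws baseline records for all patients, derives per-patient latent
#' dynamics, simulates each glucose trace at the sensor's native interval
#' (sensor1 patients first, then sensor2) and injects dropout gaps. With
#' `table5_attrition = TRUE` baseline variables are masked per patient so that
#' the number of patients holding each variable set matches the emulated
#' study's availability counts (scaled to the cohort size).
#'
#' @param config a [cohort_config()].
#' @return list with elements `series` (list of [cgm_series()]), `baseline`
#'   (data.frame, one row per patient, first column `patient_id`) and `truth`
#'   (data.frame of the latent dynamics parameters).
#' @export
#' @examples
#' co <- simulate_cohort(cohort_config(n_patients = 2, n_sensor1 = 1,
#'                                     duration_days = c(2, 2), seed = 7))
#' length(co$series)
simulate_cohort <- function(config = cohort_config()) {
  .assert(inherits(config, "cohort_config"), "config must be a cohort_config")
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%02d", seq_len(n))
  sensor <- rep(c("sensor1", "sensor2"),
                c(config$n_sensor1, n - config$n_sensor1))
  interval <- ifelse(sensor == "sensor1", config$sensor1_interval,
                     config$sensor2_interval)
  baseline <- .simulate_baseline_table(n)
  dur_choices <- seq(config$duration_days[1], config$duration_days[2])
  durations <- dur_choices[sample.int(length(dur_choices), n, replace = TRUE)]
  series <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- patient_profile(baseline[i, , drop = FALSE],
                          effect_scale = config$baseline_effect_scale,
                          patient_id = ids[i])
    tr <- simulate_glucose_trace(pr, durations[i], interval[i],
                                 sensor = sensor[i])
    series[[i]] <- inject_missingness(tr, config$missing_fraction)
    truth[[i]] <- data.frame(patient_id = ids[i], basal = pr$basal,
                             circadian_amplitude = pr$circadian_amplitude,
                             circadian_phase = pr$circadian_phase,
                             meal_amp_1 = pr$meal_amplitudes[1],
                             meal_amp_2 = pr$meal_amplitudes[2],
                             meal_amp_3 = pr$meal_amplitudes[3],
                             ar_coef = pr$ar_coef,
                             innovation_sd = pr$innovation_sd,
                             duration_days = durations[i],
                             sensor = sensor[i])
  }
  baseline <- cbind(data.frame(patient_id = ids), baseline)
  if (config$table5_attrition)
    baseline <- .apply_attrition(baseline, sensor)
  list(series = series, baseline = baseline,
       truth = do.call(rbind, truth), config = config)
}

# Mask baseline variables so per-sensor variable-set availability follows the
# emulated study's attrition counts (proportionally rescaled to cohort size).
.apply_attrition <- function(baseline, sensor) {
  for (sn in c("sensor1", "sensor2")) {
    rows <- which(sensor == sn)
    m <- length(rows)
    if (!m) next
    counts <- .attrition_counts[[sn]]
    have <- pmax(1L, round(counts / counts[1] * m))  # patients with >= set j
    # patient ranked r keeps sets j with have[j+1] >= r
    for (r in seq_len(m)) {
      deepest <- max(which(have >= r)) - 1L          # deepest set held
      keep <- variable_set_names(deepest)
      drop_cols <- setdiff(names(baseline), c("patient_id", keep))
      full <- variable_set_names(6)
      drop_cols <- intersect(drop_cols, setdiff(full, keep))
      baseline[rows[r], drop_cols] <- NA_real_
    }
  }
  baseline
}

#' Write a cohort to CSV files
#'
#' Writes `cgm.csv` (`patient_id`, ISO-8601 `timestamp`, `glucose_mgdl`,
#' `sensor`), `baseline.csv` and `truth.csv` into `dir`. Identical cohorts
#' produce byte-identical files.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths of the three files.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cgm <- do.call(rbind, lapply(cohort$series, function(s) {
    data.frame(patient_id = s$patient_id,
               timestamp = format(s$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
               glucose_mgdl = s$glucose,
               sensor = s$sensor)
  }))
  paths <- file.path(dir, c("cgm.csv", "baseline.csv", "truth.csv"))
  write.csv(cgm, paths[1], row.names = FALSE, na = "")
  write.csv(cohort$baseline, paths[2], row.names = FALSE, na = "")
  write.csv(cohort$truth, paths[3], row.names = FALSE, na = "")
  invisible(paths)
}
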