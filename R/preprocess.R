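# CGM loading, cleaning, grid resampling, imputation and scaling.

#' CGM series container
#'
#' A single patient's timestamped glucose trace. Timestamps must be strictly
#' increasing; missing samples are `NA` in `glucose`.
#'
#' @param patient_id opaque patient identifier.
#' @param time POSIXct timestamps, strictly increasing.
#' @param glucose glucose in mg/dL (`NA` = missing); present values must be
#'   positive.
#' @param sensor sensor label (`"sensor1"` or `"sensor2"`).
#' @param native_interval sampling interval in minutes; inferred from the
#'   median timestamp difference when `NULL`.
#' @return object of class `cgm_series`.
#' @export
cgm_series <- function(patient_id, time, glucose, sensor = "sensor2",
                       native_interval = NULL) {
  .assert(length(time) == length(glucose),
          "time and glucose must have equal length")
  .assert(length(time) == 0 || !is.unsorted(time, strictly = TRUE),
          "timestamps must be strictly increasing")
  .assert(all(glucose > 0, na.rm = TRUE),
          "present glucose values must be positive")
  if (is.null(native_interval)) {
    .assert(length(time) >= 2, "cannot infer native interval from < 2 samples")
    native_interval <- as.numeric(median(diff(as.numeric(time)))) / 60
  }
  structure(list(patient_id = as.character(patient_id),
                 time = as.POSIXct(time, tz = "UTC"),
                 glucose = as.numeric(glucose),
                 sensor = sensor,
                 native_interval = native_interval),
            class = "cgm_series")
}

#' @export
print.cgm_series <- function(x, ...) {
  n <- length(x$glucose)
  cat(sprintf("<cgm_series> patient %s, %s, %d samples @ %g min, %.1f%% missing\n",
              x$patient_id, x$sensor, n, x$native_interval,
              if (n) 100 * mean(is.na(x$glucose)) else 0))
  invisible(x)
}

#' @export
as.data.frame.cgm_series <- function(x, ...) {
  data.frame(patient_id = x$patient_id, time = x$time, glucose = x$glucose,
             sensor = x$sensor)
}

.parse_timestamps <- function(ts) {
  out <- as.POSIXct(ts, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  bad <- which(is.na(out) & !is.na(ts) & nzchar(ts))
  if (length(bad)) {
    out[bad] <- as.POSIXct(ts[bad], tz = "UTC",
                           tryFormats = c("%Y-%m-%d %H:%M:%OS",
                                          "%Y-%m-%d %H:%M",
                                          "%Y/%m/%d %H:%M:%OS"))
  }
  bad <- which(is.na(out))
  if (length(bad))
    stop(sprintf("unparseable timestamps at rows: %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  out
}

#' Load CGM traces from CSV
#'
#' Reads a long-format CSV with columns `patient_id`, `timestamp` (ISO-8601),
#' `glucose_mgdl` and `sensor`, returning one [cgm_series()] per patient. Rows
#' are sorted by timestamp; duplicate (patient, timestamp) rows are collapsed
#' to their mean (sensor re-transmissions).
#'
#' @param path CSV file path.
#' @return named list of [cgm_series()].
#' @export
load_cgm_csv <- function(path) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty CGM file: ", path)
    return(list())
  }
  need <- c("patient_id", "timestamp", "glucose_mgdl", "sensor")
  miss <- setdiff(need, names(df))
  .assert(length(miss) == 0,
          sprintf("missing columns in %s: %s", path, paste(miss, collapse = ", ")))
  df$time <- .parse_timestamps(df$timestamp)
  out <- lapply(split(df, df$patient_id), function(d) {
    d <- d[order(d$time), ]
    key <- as.numeric(d$time)
    if (anyDuplicated(key)) {
      g <- tapply(d$glucose_mgdl, key, function(v)
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
      keep <- !duplicated(key)
      d <- d[keep, ]
      d$glucose_mgdl <- as.numeric(g[as.character(key[keep])])
    }
    cgm_series(d$patient_id[1], d$time, d$glucose_mgdl, sensor = d$sensor[1])
  })
  out[order(names(out))]
}

#' Load a baseline table from CSV
#'
#' @param path CSV with a `patient_id` column plus baseline variables (names
#'   as in [variable_set_names()]).
#' @return data.frame with one row per patient.
#' @export
load_baseline_csv <- function(path) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  .assert("patient_id" %in% names(df), "baseline table needs a patient_id column")
  df
}

#' Missing fraction and exclusion rule
#'
#' The expected sample count is derived from the series' span on its native
#' grid (`span / native_interval + 1`); the missing fraction is
#' `1 - observed / expected`. A patient is excluded when *more than* 50% of
#' the CGM data is missing (strict inequality: exactly 50% is retained).
#'
#' @param series a [cgm_series()].
#' @return `missing_fraction()`: fraction in `[0, 1]`; `is_excluded()`:
#'   logical.
#' @export
missing_fraction <- function(series) {
  .assert(inherits(series, "cgm_series"), "series must be a cgm_series")
  n <- length(series$glucose)
  if (n == 0) return(1)
  span <- as.numeric(difftime(series$time[n], series$time[1], units = "mins"))
  expected <- span / series$native_interval + 1
  observed <- sum(!is.na(series$glucose))
  max(0, min(1, 1 - observed / expected))
}

#' @rdname missing_fraction
#' @param threshold exclusion threshold (default 0.5).
#' @export
is_excluded <- function(series, threshold = 0.5) {
  if (length(series$glucose) == 0) return(TRUE)
  missing_fraction(series) > threshold
}

.check_uniform_grid <- function(series) {
  d <- diff(as.numeric(series$time)) / 60
  .assert(all(abs(d - series$native_interval) < 1e-6),
          "series must lie on a uniform native grid for resampling")
}

#' Resample a CGM series to the common 5-min grid
#'
#' 15-min series are upsampled by linear interpolation onto the 5-min grid;
#' 1-min series are downsampled either to non-overlapping 5-min bin means
#' (default, labelled by bin start) or by decimation; 5-min series pass
#' through unchanged. Grid points adjacent to missing native samples remain
#' missing — interpolation never bridges a native gap here.
#'
#' @param series a [cgm_series()] with native interval 1, 5 or 15 min.
#' @param target_interval target spacing in minutes (5).
#' @param downsample `"mean"` (bin means) or `"decimate"`.
#' @return a [cgm_series()] on the 5-min grid.
#' @export
resample_to_grid <- function(series, target_interval = 5,
                             downsample = c("mean", "decimate")) {
  .assert(inherits(series, "cgm_series"), "series must be a cgm_series")
  downsample <- match.arg(downsample)
  ni <- series$native_interval
  .assert(ni %in% c(1, 5, 15), "unsupported native interval (must be 1, 5, 15)")
  .assert(target_interval == 5, "only the 5-min target grid is supported")
  if (ni == target_interval) return(series)
  .check_uniform_grid(series)
  v <- series$glucose
  n <- length(v)
  if (ni == 15) {
    grid_min <- seq(0, (n - 1) * ni, by = target_interval)
    obs <- which(!is.na(v))
    .assert(length(obs) >= 2, "too few observed samples to resample")
    tmin <- (seq_len(n) - 1) * ni
    out <- approx(tmin[obs], v[obs], xout = grid_min, rule = 1)$y
    # mask grid points whose bracketing native samples are not both observed
    i <- pmin(n, floor(grid_min / ni) + 1)
    on_native <- grid_min %% ni == 0
    left_ok <- !is.na(v[i])
    right_ok <- !is.na(v[pmin(n, i + 1)])
    valid <- ifelse(on_native, left_ok, left_ok & right_ok)
    out[!valid] <- NA_real_
    new_time <- series$time[1] + grid_min * 60
  } else {                              # 1-min native
    k <- target_interval / ni           # samples per bin
    nb <- floor(n / k)
    .assert(nb >= 1, "series shorter than one 5-min bin")
    vm <- matrix(v[seq_len(nb * k)], nrow = k)
    if (downsample == "mean") {
      out <- colMeans(vm, na.rm = TRUE)
      out[!is.finite(out)] <- NA_real_
    } else {
      out <- vm[1, ]
    }
    new_time <- series$time[1] + (seq_len(nb) - 1) * target_interval * 60
  }
  cgm_series(series$patient_id, new_time, out, sensor = series$sensor,
             native_interval = target_interval)
}

#' Impute interior gaps by linear interpolation
#'
#' Fills interior missing runs by linear interpolation between the flanking
#' observed values. Leading/trailing missing samples are dropped, not
#' extrapolated. Gap locations are recorded on the result as attributes:
#' `attr(x, "gaps")` (data.frame of filled runs with their length in samples
#' and minutes) and `attr(x, "imputed")` (logical vector flagging filled
#' samples) — the windowing stage uses both.
#'
#' @param series a [cgm_series()] on a uniform grid.
#' @return the imputed [cgm_series()].
#' @export
interpolate_missing <- function(series) {
  .assert(inherits(series, "cgm_series"), "series must be a cgm_series")
  v <- series$glucose
  obs <- which(!is.na(v))
  .assert(length(obs) > 0, "all-missing series cannot be interpolated")
  keep <- seq(obs[1], obs[length(obs)])
  v <- v[keep]
  tm <- series$time[keep]
  imputed <- is.na(v)
  if (any(imputed)) {
    oi <- which(!imputed)
    v <- approx(oi, v[oi], xout = seq_along(v), rule = 1)$y
  }
  out <- cgm_series(series$patient_id, tm, v, sensor = series$sensor,
                    native_interval = series$native_interval)
  r <- rle(imputed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  gi <- which(r$values)
  gaps <- data.frame(start_index = starts[gi], end_index = ends[gi],
                     n_samples = r$lengths[gi],
                     minutes = r$lengths[gi] * series$native_interval)
  if (nrow(gaps)) {
    gaps$start_time <- tm[gaps$start_index]
    gaps$end_time <- tm[gaps$end_index]
  }
  attr(out, "gaps") <- gaps
  attr(out, "imputed") <- imputed
  out
}

#' Min-max scaling
#'
#' `fit_minmax()` learns the training minimum and maximum (fit it on training
#' data only — per cross-validation fold); `apply_minmax()` maps min to 0 and
#' max to 1 linearly without clipping (test-time values outside the training
#' range map outside `[0, 1]`); `invert_minmax()` is its exact inverse. A
#' degenerate fit (max = min) maps everything to 0, with a warning.
#'
#' @param x numeric values (NAs ignored when fitting).
#' @param scaler a `scaler_state` from `fit_minmax()`.
#' @param y scaled values to invert.
#' @return `fit_minmax()`: a `scaler_state`; the others: numeric vectors.
#' @export
fit_minmax <- function(x) {
  x <- x[is.finite(x)]
  .assert(length(x) > 0, "cannot fit a scaler on no finite values")
  s <- structure(list(min = min(x), max = max(x)), class = "scaler_state")
  if (s$max == s$min)
    warning("degenerate scaler: max equals min; all values will map to 0")
  s
}

#' @rdname fit_minmax
#' @export
apply_minmax <- function(x, scaler) {
  .assert(inherits(scaler, "scaler_state"), "scaler must be a scaler_state")
  if (scaler$max == scaler$min) return(0 * x)
  (x - scaler$min) / (scaler$max - scaler$min)
}

#' @rdname fit_minmax
#' @export
invert_minmax <- function(y, scaler) {
  .assert(inherits(scaler, "scaler_state"), "scaler must be a scaler_state")
  scaler$min + y * (scaler$max - scaler$min)
}

#' Augmented Dickey-Fuller stationarity check
#'
#' Dickey-Fuller regression with constant and `max_lag` lagged differences:
#' `dy_t = a + rho * y_(t-1) + sum b_i dy_(t-i) + e_t`. The t-statistic on
#' `rho` is compared with the embedded large-sample 5% critical value for the
#' constant-only case (-2.86); the unit root is rejected when the statistic
#' falls below it. This is a quality check on each patient's trace — it never
#' gates the pipeline.
#'
#' @param series a [cgm_series()] or numeric vector (NAs dropped).
#' @param max_lag number of lagged differences; default is the Schwert rule
#'   `floor(12 * (n/100)^0.25)`.
#' @return list with `statistic`, `reject_unit_root`, `critical_value`,
#'   `lags`, `n`. For series shorter than 50 observed samples the statistic is
#'   `NA` and `flagged` is `TRUE`.
#' @export
adf_check <- function(series, max_lag = NULL) {
  v <- if (inherits(series, "cgm_series")) series$glucose else as.numeric(series)
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 50) {
    warning("fewer than 50 observed samples: ADF statistic undefined")
    return(list(statistic = NA_real_, reject_unit_root = NA,
                critical_value = -2.86, lags = NA_integer_, n = n,
                flagged = TRUE))
  }
  p <- if (is.null(max_lag)) floor(12 * (n / 100) ^ 0.25) else as.integer(max_lag)
  p <- max(0L, min(p, n - 10L))
  dv <- diff(v)
  if (p == 0) {
    y <- dv
    X <- cbind(1, v[-n])
  } else {
    E <- embed(dv, p + 1)               # col1 = dy_t, cols 2.. = lagged diffs
    y <- E[, 1]
    X <- cbind(1, v[(p + 1):(n - 1)], E[, -1, drop = FALSE])
  }
  fit <- tryCatch(lm.fit(X, y), error = function(e) NULL)
  stat <- NA_real_
  if (!is.null(fit) && is.finite(fit$coefficients[2])) {
    df <- length(y) - fit$rank
    sigma2 <- if (df > 0) sum(fit$residuals ^ 2) / df else NA_real_
    se2 <- tryCatch(sigma2 * chol2inv(chol(crossprod(X)))[2, 2],
                    error = function(e) NA_real_)
    if (is.finite(se2) && se2 > 0) stat <- fit$coefficients[2] / sqrt(se2)
  }
  list(statistic = unname(stat),
       reject_unit_root = if (is.finite(stat)) unname(stat < -2.86) else NA,
       critical_value = -2.86, lags = p, n = n, flagged = !is.finite(stat))
}
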