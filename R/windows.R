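# Supervised window construction and leave-one-day-out fold assignment.

#' Prediction-horizon specification
#'
#' @param minutes lead time between the last observed sample and the target;
#'   one of 15, 30, 60.
#' @return list with `minutes` and `steps` (number of 5-min steps; 3, 6 or
#'   12), class `horizon_spec`.
#' @export
horizon_spec <- function(minutes) {
  if (inherits(minutes, "horizon_spec")) return(minutes)
  .assert(length(minutes) == 1 && minutes %in% c(15, 30, 60),
          "prediction horizon must be 15, 30 or 60 minutes")
  structure(list(minutes = as.integer(minutes),
                 steps = as.integer(minutes / 5)), class = "horizon_spec")
}

#' Build supervised (window, target) pairs from one series
#'
#' Slides a 6-sample input window (t0..t5, 5-min spacing) over the resampled,
#' imputed series with a stride of one grid step (configurable) and takes the
#' sample `horizon` minutes after t5 as the target. A candidate is dropped
#' when its full span (inputs through target) crosses a calendar-day boundary
#' — this is what makes leave-one-day-out folds leakage-free — or crosses a
#' recorded gap longer than `max_gap_minutes`. Windows touching shorter
#' (interpolated) gaps are kept but flagged. For a contiguous single-day
#' series of L samples the window count is `max(0, L - 6 - h + 1)` with `h`
#' the horizon in steps.
#'
#' Values are stored in mg/dL unless a fitted `scaler` is supplied, in which
#' case inputs and targets are min-max scaled and the scaler is kept on the
#' dataset.
#'
#' @param series a [cgm_series()] on the 5-min grid (see
#'   [interpolate_missing()]).
#' @param horizon a [horizon_spec()] or 15/30/60.
#' @param scaler optional `scaler_state`; `NULL` keeps raw mg/dL.
#' @param input_len input window length in samples (6).
#' @param stride step between consecutive window starts, in grid samples.
#' @param max_gap_minutes windows crossing an interpolated gap longer than
#'   this are dropped.
#' @return object of class `windowed_dataset`: list with matrix `inputs`
#'   (#windows x 6), vector `targets`, `patient_id`, `target_time`, `day`
#'   (calendar date of the target), `interpolated` flags, `horizon`, `scaled`,
#'   `scaler`.
#' @export
make_windows <- function(series, horizon, scaler = NULL, input_len = 6L,
                         stride = 1L, max_gap_minutes = 15) {
  .assert(inherits(series, "cgm_series"), "series must be a cgm_series")
  .assert(series$native_interval == 5,
          "windows are built on the 5-min grid; resample first")
  h <- horizon_spec(horizon)$steps
  L <- length(series$glucose)
  v <- series$glucose
  .assert(!anyNA(v), "series still contains missing values; impute first")
  span <- input_len + h                 # offsets 0..span-1, target at span-1
  empty <- function() {
    structure(list(inputs = matrix(numeric(0), 0, input_len),
                   targets = numeric(0), patient_id = character(0),
                   target_time = series$time[0],
                   day = as.Date(character(0)),
                   interpolated = logical(0),
                   horizon = horizon_spec(horizon), scaled = !is.null(scaler),
                   scaler = scaler), class = "windowed_dataset")
  }
  if (L < span) {
    warning("series shorter than input window + horizon: empty dataset")
    return(empty())
  }
  starts <- seq.int(1L, L - span + 1L, by = stride)
  day_all <- as.Date(series$time, tz = "UTC")
  # same calendar day over the whole span
  ok_day <- day_all[starts] == day_all[starts + span - 1L]
  imputed <- attr(series, "imputed") %||% rep(FALSE, L)
  gaps <- attr(series, "gaps")
  long_gap <- rep(FALSE, L)
  if (!is.null(gaps) && nrow(gaps)) {
    gl <- gaps[gaps$minutes > max_gap_minutes, , drop = FALSE]
    for (i in seq_len(nrow(gl)))
      long_gap[gl$start_index[i]:gl$end_index[i]] <- TRUE
  }
  cs_long <- c(0, cumsum(long_gap))
  cs_imp <- c(0, cumsum(imputed))
  ends <- starts + span - 1L
  ok_gap <- (cs_long[ends + 1L] - cs_long[starts]) == 0
  keep <- which(ok_day & ok_gap)
  if (!length(keep)) {
    warning("no admissible windows (day boundaries / long gaps)")
    return(empty())
  }
  s <- starts[keep]
  idx <- outer(s, 0:(input_len - 1L), `+`)
  inputs <- matrix(v[idx], nrow = length(s))
  tgt_idx <- s + span - 1L
  targets <- v[tgt_idx]
  interp <- (cs_imp[tgt_idx + 1L] - cs_imp[s - 1L + 1L]) > 0
  if (!is.null(scaler)) {
    inputs <- apply_minmax(inputs, scaler)
    targets <- apply_minmax(targets, scaler)
  }
  structure(list(inputs = inputs, targets = targets,
                 patient_id = rep(series$patient_id, length(s)),
                 target_time = series$time[tgt_idx],
                 day = day_all[tgt_idx],
                 interpolated = interp,
                 horizon = horizon_spec(horizon),
                 scaled = !is.null(scaler), scaler = scaler),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %d windows, horizon %d min, %d patients, %d days%s\n",
              n_windows(x), x$horizon$minutes, length(unique(x$patient_id)),
              length(unique(x$day)), if (x$scaled) ", scaled" else " (mg/dL)"))
  invisible(x)
}

#' Number of windows in a dataset
#' @param ds a `windowed_dataset`.
#' @return integer count.
#' @export
n_windows <- function(ds) nrow(ds$inputs)

#' Subset or thin a windowed dataset
#'
#' `subset_windows()` keeps the given window indices; `thin_windows()` keeps
#' every `stride`-th window (a problem-size control for study-scale runs).
#'
#' @param ds a `windowed_dataset`.
#' @param idx integer indices to keep.
#' @return a `windowed_dataset`.
#' @export
subset_windows <- function(ds, idx) {
  out <- ds
  out$inputs <- ds$inputs[idx, , drop = FALSE]
  for (f in c("targets", "patient_id", "target_time", "day", "interpolated"))
    out[[f]] <- ds[[f]][idx]
  out
}

#' @rdname subset_windows
#' @param stride keep one window in every `stride`.
#' @export
thin_windows <- function(ds, stride) {
  .assert(stride >= 1, "stride must be >= 1")
  subset_windows(ds, seq.int(1L, n_windows(ds), by = stride))
}

#' Combine windowed datasets across patients
#'
#' @param ds_list list of `windowed_dataset`s with the same horizon and
#'   scaling state.
#' @return a pooled `windowed_dataset`.
#' @export
combine_windows <- function(ds_list) {
  ds_list <- Filter(function(d) n_windows(d) > 0, ds_list)
  .assert(length(ds_list) > 0, "no non-empty datasets to combine")
  h <- vapply(ds_list, function(d) d$horizon$minutes, numeric(1))
  .assert(length(unique(h)) == 1, "datasets have different horizons")
  sc <- vapply(ds_list, function(d) d$scaled, logical(1))
  .assert(length(unique(sc)) == 1, "datasets have mixed scaling states")
  out <- ds_list[[1]]
  out$inputs <- do.call(rbind, lapply(ds_list, `[[`, "inputs"))
  out$targets <- unlist(lapply(ds_list, `[[`, "targets"), use.names = FALSE)
  out$patient_id <- unlist(lapply(ds_list, `[[`, "patient_id"), use.names = FALSE)
  out$target_time <- do.call(c, lapply(ds_list, `[[`, "target_time"))
  out$day <- do.call(c, lapply(ds_list, `[[`, "day"))
  out$interpolated <- unlist(lapply(ds_list, `[[`, "interpolated"), use.names = FALSE)
  out
}

#' Leave-one-day-out cross-validation folds
#'
#' One fold per distinct calendar day, pooled across patients: the fold's test
#' set is every window whose target falls on that day, and its training set is
#' everything else (days before and after the held-out day combined). Test
#' sets partition the dataset.
#'
#' @param ds a `windowed_dataset` with at least two distinct days.
#' @return list of folds, each `list(day, train, test)` with integer indices.
#' @export
leave_one_day_out_folds <- function(ds) {
  days <- sort(unique(ds$day))
  .assert(length(days) >= 2,
          "leave-one-day-out needs at least 2 distinct days")
  lapply(days, function(d) {
    test <- which(ds$day == d)
    list(day = d, train = setdiff(seq_len(n_windows(ds)), test), test = test)
  })
}
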