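# Cross-validated evaluation: leave-one-day-out training/prediction, error
# metrics (percentage and mg/dL point error), hypo/hyper stratification and
# paired significance tests.

#' Leave-one-day-out cross-validation
#'
#' For each distinct calendar day: fit a min-max scaler on the training
#' windows only, train the model from a fresh fold-seeded initialisation, and
#' predict the held-out day's windows in mg/dL.
#'
#' @param windows an *unscaled* `windowed_dataset` (mg/dL) pooled over
#'   patients.
#' @param baseline baseline table (multimodal mode).
#' @param mode `"unimodal"` or `"multimodal"`.
#' @param control a [model_config()]; fold `k` trains with seed
#'   `control$seed + k`.
#' @param verbose print per-fold progress.
#' @return object of class `glucast_cv`: per-fold results (`day`, `actual`,
#'   `predicted`, `patient_id`) plus the pooled prediction table.
#' @export
cv_glucast <- function(windows, baseline = NULL,
                       mode = c("unimodal", "multimodal"),
                       control = model_config(), verbose = FALSE) {
  mode <- match.arg(mode)
  .assert(!windows$scaled, "cross-validation needs an unscaled (mg/dL) dataset")
  folds <- leave_one_day_out_folds(windows)
  results <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    f <- folds[[k]]
    .assert(length(f$train) > 0, "fold with empty training set")
    tr <- subset_windows(windows, f$train)
    te <- subset_windows(windows, f$test)
    scaler <- fit_minmax(c(tr$inputs, tr$targets))
    ctl <- control
    ctl$seed <- control$seed + k
    model <- glucast(tr, baseline = baseline, mode = mode, control = ctl,
                     scaler = scaler)
    pred <- predict(model, te, baseline = baseline)
    results[[k]] <- list(day = f$day, actual = te$targets,
                         predicted = pred, patient_id = te$patient_id)
    if (verbose)
      message(sprintf("fold %d/%d (day %s): %d test windows, MAE %.2f mg/dL",
                      k, length(folds), f$day, length(pred),
                      mean(abs(pred - te$targets))))
  }
  pooled <- data.frame(
    day = as.Date(unlist(lapply(results, function(r)
      rep(as.character(r$day), length(r$actual))))),
    patient_id = unlist(lapply(results, `[[`, "patient_id")),
    actual = unlist(lapply(results, `[[`, "actual")),
    predicted = unlist(lapply(results, `[[`, "predicted")))
  structure(list(folds = results, pooled = pooled, mode = mode,
                 horizon = windows$horizon, config = control),
            class = "glucast_cv")
}

#' @export
print.glucast_cv <- function(x, ...) {
  cat(sprintf("<glucast_cv> %s, horizon %d min: %d folds, %d predictions\n",
              x$mode, x$horizon$minutes, length(x$folds), nrow(x$pooled)))
  cat(sprintf("  pooled MAPE %.2f%%, mean absolute point error %.2f mg/dL\n",
              mape_percent(x$pooled$actual, x$pooled$predicted),
              mean_absolute_point_error(x$pooled$actual, x$pooled$predicted)))
  invisible(x)
}

#' @export
summary.glucast_cv <- function(object, ...) {
  s <- stratified_metrics(object$pooled$actual, object$pooled$predicted)
  per_fold <- data.frame(
    day = as.Date(vapply(object$folds, function(f) as.character(f$day), "")),
    n = vapply(object$folds, function(f) length(f$actual), 0),
    mape_pct = vapply(object$folds, function(f)
      mape_percent(f$actual, f$predicted), 0),
    mae_mgdl = vapply(object$folds, function(f)
      mean_absolute_point_error(f$actual, f$predicted), 0))
  out <- list(stratified = s, per_fold = per_fold, mode = object$mode,
              horizon = object$horizon$minutes)
  class(out) <- "summary.glucast_cv"
  out
}

#' @export
print.summary.glucast_cv <- function(x, ...) {
  cat(sprintf("%s forecaster, %d-min horizon, %d leave-one-day-out folds\n",
              x$mode, x$horizon, nrow(x$per_fold)))
  print(x$stratified, row.names = FALSE)
  invisible(x)
}

#' @export
plot.glucast_cv <- function(x, ...) {
  ape <- abs(x$pooled$actual - x$pooled$predicted)
  boxplot(ape ~ format(x$pooled$day), xlab = "held-out day",
          ylab = "absolute point error (mg/dL)",
          main = sprintf("%s, %d-min horizon", x$mode, x$horizon$minutes), ...)
  invisible(x)
}

#' Mean absolute percentage error
#'
#' `100 * mean(|actual - predicted| / actual)`; requires strictly positive
#' actual values.
#'
#' @param actual,predicted equal-length mg/dL vectors.
#' @return percentage.
#' @export
#' @examples
#' mape_percent(c(100, 200), c(90, 220))  # 10
mape_percent <- function(actual, predicted) {
  .assert(length(actual) == length(predicted) && length(actual) > 0,
          "actual and predicted must be equal-length and non-empty")
  .assert(all(actual > 0), "actual values must be strictly positive")
  100 * mean(abs(actual - predicted) / actual)
}

#' Mean absolute point error (mg/dL)
#'
#' `mean(|actual - predicted|)` in the measurement units.
#'
#' @param actual,predicted equal-length mg/dL vectors.
#' @return error in mg/dL.
#' @export
#' @examples
#' mean_absolute_point_error(c(100, 200), c(90, 220))  # 15
mean_absolute_point_error <- function(actual, predicted) {
  .assert(length(actual) == length(predicted) && length(actual) > 0,
          "actual and predicted must be equal-length and non-empty")
  mean(abs(actual - predicted))
}

#' Overall and hypo-/hyperglycaemia-stratified error metrics
#'
#' Strata are defined on the *acquired* (actual) values: hyperglycaemic
#' (actual > 180 mg/dL) and hypoglycaemic (actual < 70 mg/dL). Both the
#' percentage and the mg/dL point-error forms are reported side by side (the
#' two metrics are deliberately kept distinct). An empty stratum yields `NA`
#' (undefined), not zero.
#'
#' @param actual,predicted equal-length mg/dL vectors.
#' @return data.frame with rows overall/hyperglycaemic/hypoglycaemic and
#'   columns `n`, `mape_pct`, `mae_mgdl`.
#' @export
stratified_metrics <- function(actual, predicted) {
  strata <- list(overall = rep(TRUE, length(actual)),
                 hyperglycaemic = actual > 180,
                 hypoglycaemic = actual < 70)
  rows <- lapply(names(strata), function(nm) {
    i <- strata[[nm]]
    if (!any(i)) return(data.frame(stratum = nm, n = 0L, mape_pct = NA_real_,
                                   mae_mgdl = NA_real_))
    data.frame(stratum = nm, n = sum(i),
               mape_pct = mape_percent(actual[i], predicted[i]),
               mae_mgdl = mean_absolute_point_error(actual[i], predicted[i]))
  })
  do.call(rbind, rows)
}

#' Paired t-test on per-point absolute errors
#'
#' Compares two models scored on the same test points via a two-sided paired
#' t-test on their absolute errors, with the usual significance stars
#' (* p < 0.05, ** p < 0.01, *** p < 0.001). Degenerate cases: all-zero
#' differences give p = 1; equal nonzero differences (zero variance) are
#' flagged and given p = 0.
#'
#' @param errors_a,errors_b equal-length error vectors (n >= 2), e.g.
#'   absolute errors of two architectures on the same windows.
#' @return list with `t`, `p`, `stars`, `degenerate`.
#' @export
paired_t_test <- function(errors_a, errors_b) {
  .assert(length(errors_a) == length(errors_b), "error vectors differ in length")
  n <- length(errors_a)
  .assert(n >= 2, "paired test needs at least 2 points")
  d <- errors_a - errors_b
  sd_d <- sd(d)
  if (sd_d == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, stars = "", degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = 0, stars = "***",
                degenerate = TRUE))
  }
  tstat <- mean(d) / (sd_d / sqrt(n))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  list(t = tstat, p = p, stars = stars, degenerate = FALSE)
}

#' Last-value persistence baseline
#'
#' Naive forecast: the prediction is the last observed input sample (t5).
#'
#' @param windows an unscaled `windowed_dataset`.
#' @return vector of mg/dL predictions, one per window.
#' @export
persistence_forecast <- function(windows) {
  .assert(!windows$scaled, "persistence baseline expects mg/dL values")
  windows$inputs[, ncol(windows$inputs)]
}
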