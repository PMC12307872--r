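# The classed modelling interface: glucast() fits the forecaster on a
# windowed dataset and returns an object with the usual methods.

#' Fit the glucose forecaster
#'
#' Trains the BiLSTM -> self-attention -> CNN sequence encoder (optionally
#' fused with a dense encoder of baseline variables) on a windowed dataset by
#' mini-batch Adam. Inputs and targets are min-max scaled with a scaler fitted
#' on this (training) data unless the dataset is already scaled or a scaler is
#' supplied; predictions are returned in mg/dL by inverting the scaler.
#'
#' @param windows a `windowed_dataset` from [make_windows()] /
#'   [combine_windows()].
#' @param baseline data.frame with `patient_id` plus the baseline variables of
#'   the configured set (multimodal mode only; values are used unscaled).
#' @param mode `"unimodal"` or `"multimodal"`.
#' @param control a [model_config()].
#' @param scaler optional pre-fitted `scaler_state` (e.g. the fold's training
#'   scaler during cross-validation).
#' @return object of class `glucast` with `print()`, `summary()`, `coef()`,
#'   `predict()`, `fitted()`, `residuals()` and `plot()` methods.
#' @seealso [cv_glucast()] for leave-one-day-out cross-validation.
#' @export
#' @examples
#' set.seed(42)
#' co <- simulate_cohort(cohort_config(n_patients = 2, n_sensor1 = 0,
#'                                     duration_days = c(2, 2),
#'                                     missing_fraction = 0, seed = 42))
#' ds <- combine_windows(lapply(co$series, function(s)
#'   make_windows(interpolate_missing(resample_to_grid(s)), 30)))
#' fit <- glucast(thin_windows(ds, 12), control = model_config(
#'   lstm_hidden = 4, cnn_filters = 8, epochs = 2, batch_size = 32))
#' fit
glucast <- function(windows, baseline = NULL,
                    mode = c("unimodal", "multimodal"),
                    control = model_config(), scaler = NULL) {
  .assert(inherits(windows, "windowed_dataset"), "windows must be a windowed_dataset")
  mode <- match.arg(mode)
  control$mode <- mode
  .assert(n_windows(windows) > 0, "cannot fit on an empty dataset")
  if (windows$scaled) {
    scaler <- windows$scaler
    X <- windows$inputs
    y <- windows$targets
  } else {
    if (is.null(scaler))
      scaler <- fit_minmax(c(windows$inputs, windows$targets))
    X <- apply_minmax(windows$inputs, scaler)
    y <- apply_minmax(windows$targets, scaler)
  }
  R <- NULL
  vars <- NULL
  if (mode == "multimodal") {
    .assert(!is.null(baseline), "multimodal mode needs a baseline table")
    vars <- variable_set_names(control$variable_set)
    R <- .records_for(windows$patient_id, baseline, vars)
  }
  fit <- .train_network(X, y, R, windows$patient_id, control)
  fitted_scaled <- .predict_scaled(X, R, fit$params, control)
  structure(list(params = fit$params, config = control, scaler = scaler,
                 loss_trace = fit$trace, mode = mode,
                 horizon = windows$horizon,
                 variable_names = vars, baseline = baseline,
                 n_windows = n_windows(windows),
                 patients = unique(windows$patient_id),
                 targets_mgdl = invert_minmax(y, scaler),
                 fitted_mgdl = invert_minmax(fitted_scaled, scaler),
                 call = match.call()),
            class = "glucast")
}

# ordered, complete record matrix for each window's patient
.records_for <- function(patient_id, baseline, vars) {
  .assert("patient_id" %in% names(baseline),
          "baseline table needs a patient_id column")
  miss <- setdiff(vars, names(baseline))
  .assert(length(miss) == 0,
          sprintf("baseline table lacks variables: %s", paste(miss, collapse = ", ")))
  rows <- match(patient_id, baseline$patient_id)
  .assert(!anyNA(rows), "baseline table lacks some patients in the dataset")
  R <- as.matrix(baseline[rows, vars, drop = FALSE])
  if (anyNA(R))
    stop("baseline variables absent for some patients; drop them first with ",
         "filter_variable_set()", call. = FALSE)
  storage.mode(R) <- "double"
  R
}

# predict in scaled space, chunked to bound memory
.predict_scaled <- function(X, R, params, config, chunk = 4096L) {
  n <- nrow(X)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    out[s:e] <- .forward_batch(X[s:e, , drop = FALSE],
                               if (is.null(R)) NULL else R[s:e, , drop = FALSE],
                               params, config, training = FALSE)$yhat
  }
  out
}

#' Drop windows of patients lacking a variable set
#'
#' Reproduces the availability-attrition mechanism: patients whose baseline
#' record lacks any variable of the active set are removed before fold
#' construction.
#'
#' @param windows a `windowed_dataset`.
#' @param baseline baseline data.frame.
#' @param set variable set (0..6).
#' @return the filtered `windowed_dataset`.
#' @export
filter_variable_set <- function(windows, baseline, set) {
  vars <- variable_set_names(set)
  miss <- setdiff(vars, names(baseline))
  .assert(length(miss) == 0,
          sprintf("baseline table lacks variables: %s", paste(miss, collapse = ", ")))
  ok <- baseline$patient_id[stats::complete.cases(baseline[, vars, drop = FALSE])]
  subset_windows(windows, which(windows$patient_id %in% ok))
}

#' @export
print.glucast <- function(x, ...) {
  cat(sprintf("<glucast> %s forecaster, horizon %d min\n",
              x$mode, x$horizon$minutes))
  cat(sprintf("  trained on %d windows from %d patients (%d epochs)\n",
              x$n_windows, length(x$patients), x$config$epochs))
  if (x$mode == "multimodal")
    cat("  baseline variables:", paste(x$variable_names, collapse = ", "), "\n")
  cat(sprintf("  final training loss (%s, scaled): %.5g\n",
              x$config$loss, tail(x$loss_trace, 1)))
  invisible(x)
}

#' @export
summary.glucast <- function(object, ...) {
  res <- object$targets_mgdl - object$fitted_mgdl
  out <- list(mode = object$mode, horizon = object$horizon$minutes,
              n_windows = object$n_windows,
              n_patients = length(object$patients),
              n_parameters = length(.flatten_params(object$params)),
              loss_first = object$loss_trace[1],
              loss_final = tail(object$loss_trace, 1),
              train_mae_mgdl = mean(abs(res)),
              train_mape_pct = mape_percent(object$targets_mgdl,
                                            object$fitted_mgdl))
  class(out) <- "summary.glucast"
  out
}

#' @export
print.summary.glucast <- function(x, ...) {
  cat(sprintf("%s glucose forecaster, %d-min horizon\n", x$mode, x$horizon))
  cat(sprintf("  windows: %d   patients: %d   parameters: %d\n",
              x$n_windows, x$n_patients, x$n_parameters))
  cat(sprintf("  training loss: %.5g -> %.5g\n", x$loss_first, x$loss_final))
  cat(sprintf("  training MAE: %.2f mg/dL   training MAPE: %.2f%%\n",
              x$train_mae_mgdl, x$train_mape_pct))
  invisible(x)
}

#' @export
coef.glucast <- function(object, ...) object$params

#' Predict glucose for new windows
#'
#' @param object fitted [glucast()] model.
#' @param newdata a `windowed_dataset` in mg/dL (unscaled) or scaled with the
#'   model's own scaler; `NULL` returns fitted values.
#' @param baseline baseline table for multimodal models (defaults to the one
#'   used at fit time).
#' @param type `"response"` for mg/dL, `"scaled"` for the sigmoid output.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.glucast <- function(object, newdata = NULL, baseline = NULL,
                            type = c("response", "scaled"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(if (type == "response") object$fitted_mgdl
           else apply_minmax(object$fitted_mgdl, object$scaler))
  }
  .assert(inherits(newdata, "windowed_dataset"), "newdata must be a windowed_dataset")
  X <- if (newdata$scaled) newdata$inputs
       else apply_minmax(newdata$inputs, object$scaler)
  R <- NULL
  if (object$mode == "multimodal") {
    bl <- baseline %||% object$baseline
    .assert(!is.null(bl), "multimodal prediction needs a baseline table")
    R <- .records_for(newdata$patient_id, bl, object$variable_names)
  }
  yhat <- .predict_scaled(X, R, object$params, object$config)
  if (type == "response") invert_minmax(yhat, object$scaler) else yhat
}

#' @export
fitted.glucast <- function(object, ...) object$fitted_mgdl

#' @export
residuals.glucast <- function(object, ...) object$targets_mgdl - object$fitted_mgdl

#' @export
plot.glucast <- function(x, ...) {
  plot(seq_along(x$loss_trace), x$loss_trace, type = "b", pch = 16,
       xlab = "epoch", ylab = sprintf("training loss (%s, scaled)", x$config$loss),
       main = sprintf("%s forecaster, %d-min horizon", x$mode,
                      x$horizon$minutes), ...)
  invisible(x)
}
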