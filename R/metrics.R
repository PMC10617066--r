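#' Chemometric evaluation metrics
#'
#' The standard metric suite for spectroscopic calibration models:
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot`, median absolute
#' error (even sample counts take the midpoint of the central pair), mean
#' absolute percentage error (in percent; undefined when any truth is zero),
#' root mean squared error on the prediction/test set, the same formula on
#' the calibration/training set (RMSEC), and the residual predictive
#' deviation `RPD = 1 / sqrt(1 - R^2)` -- larger RPD means a more accurate
#' calibration. All metrics are permutation-invariant over samples.
#'
#' @param y Actual values.
#' @param yhat Predicted values (same length).
#' @return A single numeric value.
#' @examples
#' metric_r2(c(1, 2, 3), c(1, 2, 4))   # 0.5
#' metric_mape(c(1, 2), c(1.1, 1.8))   # 10
#' rpd(0.75)                           # 2
#' @name metrics
NULL

check_pair <- function(y, yhat, min_n = 1) {
  if (length(y) != length(yhat)) stop_shape("y and yhat must have equal length")
  if (length(y) < min_n) stop_value(paste0("need at least ", min_n, " samples"))
}

#' @rdname metrics
#' @export
metric_r2 <- function(y, yhat) {
  check_pair(y, yhat, min_n = 2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop_metric("R^2 is undefined for constant y")
  1 - sum((y - yhat)^2) / ss_tot
}

#' @rdname metrics
#' @export
metric_medae <- function(y, yhat) {
  check_pair(y, yhat)
  stats::median(abs(y - yhat))
}

#' @rdname metrics
#' @export
metric_mape <- function(y, yhat) {
  check_pair(y, yhat)
  if (any(y == 0)) stop_metric("MAPE is undefined when any y is zero")
  100 * mean(abs((y - yhat) / y))
}

#' @rdname metrics
#' @export
metric_rmse <- function(y, yhat) {
  check_pair(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' @rdname metrics
#' @export
metric_rmsec <- function(y, yhat) metric_rmse(y, yhat)

#' @rdname metrics
#' @param r2 An R-squared value `< 1`.
#' @export
rpd <- function(r2) {
  if (!is.finite(r2) || r2 >= 1) {
    stop_metric("RPD is unbounded for R^2 >= 1")
  }
  1 / sqrt(1 - r2)
}

#' Assemble the six-metric model report
#'
#' Computes the full evaluation row on the concentration (ppm) scale:
#' `R2`, `MedAE`, `MAPE`, `RMSE` and `RPD` on the test set and `RMSEC` on
#' the training set. RPD is always derived from the unrounded `R2`; a
#' perfect test fit (`R2 == 1`) reports `RPD = Inf` rather than failing, so
#' the report stays constructible.
#'
#' @param y_test,yhat_test Actual and predicted test concentrations (ppm).
#' @param y_train,yhat_train Actual and predicted training concentrations.
#' @return A one-row tibble with columns `R2`, `MedAE`, `MAPE`, `RMSE`,
#'   `RPD`, `RMSEC`.
#' @export
metrics_report <- function(y_test, yhat_test, y_train, yhat_train) {
  r2 <- metric_r2(y_test, yhat_test)
  tibble::tibble(
    R2 = r2,
    MedAE = metric_medae(y_test, yhat_test),
    MAPE = metric_mape(y_test, yhat_test),
    RMSE = metric_rmse(y_test, yhat_test),
    RPD = if (r2 >= 1) Inf else rpd(r2),
    RMSEC = metric_rmsec(y_train, yhat_train)
  )
}

#' Evaluate a model on held-out spectra
#'
#' Predicts both sets with the model, inverse-transforms predictions to ppm
#' through the scaler, and builds the [metrics_report()].
#'
#' @param model A `sers_cnn` model trained on scaled features.
#' @param train,test Scaled [spectra_tbl][as_spectra]s carrying ppm labels.
#' @param scaler The [fit_scaler()] state used for training.
#' @return A one-row metrics tibble.
#' @export
evaluate_model <- function(model, train, test, scaler) {
  y_train <- unname(spectra_concentrations(train))
  y_test <- unname(spectra_concentrations(test))
  if (any(is.na(y_train)) || any(is.na(y_test))) {
    stop_value("evaluation requires fully labeled train and test sets")
  }
  metrics_report(
    y_test, predict(model, test, scaler = scaler),
    y_train, predict(model, train, scaler = scaler)
  )
}
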