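#' Run the full synthetic calibration experiment
#'
#' End-to-end reproduction of the calibration workflow on synthetic SERS
#' data: simulate the concentration gradient, airPLS-correct each spectrum,
#' keep the characteristic windows, split into train/test across the
#' gradient, min-max scale features (and divide targets by the top
#' concentration), search initial weights with the adaptive GA, train the
#' separable residual CNN under the kernel-Huber loss, and evaluate on the
#' ppm scale. One root `seed` drives every stage through [derive_seed()], so
#' two runs with the same seed are identical.
#'
#' @param seed Root seed.
#' @param synth A [synth_config()]; its own seed is overridden by the root
#'   seed fan-out.
#' @param lam,max_iter,ratio_tol airPLS settings (see [airpls_baseline()]).
#' @param windows A [window_set()].
#' @param n_train Training-set size of the gradient split.
#' @param delta,sigma Kernel-Huber loss settings (see [kernel_huber()]).
#' @param ga A [ga_config()] (seed overridden); `NULL` skips the genetic
#'   initial-weight search.
#' @param lr,epochs Gradient-training settings (see [train_network()]).
#' @param augment Multiplier on the generator's detector-noise level used
#'   for train-time input augmentation (`augment * noise_sd`, rescaled to
#'   the min-max feature axis); `0` disables augmentation.
#' @param average_tail Fraction of final epochs averaged into the returned
#'   weights (see [train_network()]).
#' @param model_cfg Optional [cnn_config()]; defaults to the standard small
#'   architecture sized to the selected windows.
#' @return A `sers_fit` object: a list with the fitted `model`, `scaler`,
#'   `metrics` (one-row tibble), per-sample `predictions` tibble, training
#'   `history`, the `ga` result, and the configurations used. Supports
#'   `print()`, `tidy()` (predictions), `glance()` (metrics) and
#'   `autoplot()`.
#' @examples
#' \donttest{
#' fit <- run_pipeline(seed = 1, synth = synth_config(n_samples = 12),
#'                     ga = ga_config(pop_size = 4, generations = 2),
#'                     epochs = 10)
#' glance(fit)
#' }
#' @export
run_pipeline <- function(seed = 1,
                         synth = synth_config(),
                         lam = 1e5, max_iter = 15, ratio_tol = 0.001,
                         windows = default_windows(),
                         n_train = 40,
                         delta = 1, sigma = "auto",
                         ga = ga_config(),
                         lr = 5e-3, epochs = 2500,
                         augment = 1, average_tail = 1/3,
                         model_cfg = NULL) {
  synth$seed <- derive_seed(seed, 1)
  sim <- generate_spectra(synth)
  corrected <- correct_baseline(sim$spectra, lam = lam, max_iter = max_iter,
                                ratio_tol = ratio_tol)
  selected <- select_windows(corrected, windows)
  sets <- split_spectra(selected, n_train = n_train, seed = derive_seed(seed, 2))
  scaler <- fit_scaler(sets$train, conc_max = synth$conc_max)
  train_sc <- scale_spectra(sets$train, scaler)
  test_sc <- scale_spectra(sets$test, scaler)
  x_train <- spectra_matrix(train_sc)
  y_train <- scale_concentration(unname(spectra_concentrations(train_sc)), scaler)

  if (is.null(model_cfg)) {
    model_cfg <- cnn_config(input_length = ncol(x_train),
                            seed = derive_seed(seed, 3))
  }
  model <- build_model(model_cfg)

  ga_result <- NULL
  init <- NULL
  if (!is.null(ga)) {
    ga$seed <- derive_seed(seed, 4)
    ga_result <- run_ga(model, x_train, y_train, ga)
    init <- ga_result$best
  }
  aug_sd <- if (augment > 0) augment * synth$noise_sd / scaler$ranges else 0
  trained <- train_network(model, x_train, y_train, delta = delta,
                           sigma = sigma, lr = lr, epochs = epochs,
                           augment_sd = aug_sd, seed = derive_seed(seed, 5),
                           average_tail = average_tail, init = init)

  metrics <- evaluate_model(trained$model, train_sc, test_sc, scaler)
  predictions <- dplyr::bind_rows(
    tibble::tibble(
      sample_id = spectra_ids(train_sc), set = "train",
      actual_ppm = unname(spectra_concentrations(train_sc)),
      predicted_ppm = predict(trained$model, train_sc, scaler = scaler)
    ),
    tibble::tibble(
      sample_id = spectra_ids(test_sc), set = "test",
      actual_ppm = unname(spectra_concentrations(test_sc)),
      predicted_ppm = predict(trained$model, test_sc, scaler = scaler)
    )
  )
  structure(
    list(seed = seed, synth = synth, windows = windows, n_train = n_train,
         loss = list(delta = delta, sigma = sigma),
         model = trained$model, scaler = scaler, ga = ga_result,
         history = trained$history, metrics = metrics,
         predictions = predictions),
    class = "sers_fit"
  )
}

#' @export
print.sers_fit <- function(x, ...) {
  cat("<sers_fit> kernel-Huber GA-CNN calibration on synthetic SERS data\n")
  cat("  seed:", x$seed, "  samples:",
      length(unique(x$predictions$sample_id)), "\n")
  cat("  test metrics (ppm scale):\n")
  m <- x$metrics
  cat(sprintf("    R2 = %.4f  MedAE = %.3f  MAPE = %.2f%%\n",
              m$R2, m$MedAE, m$MAPE))
  cat(sprintf("    RMSE = %.3f  RPD = %.2f  RMSEC = %.3f\n",
              m$RMSE, m$RPD, m$RMSEC))
  invisible(x)
}

#' @export
tidy.sers_fit <- function(x, ...) x$predictions

#' @importFrom generics glance
#' @export
glance.sers_fit <- function(x, ...) x$metrics

#' Predicted-versus-actual calibration plot
#'
#' Scatter of predicted against actual concentration on log-log axes, train
#' and test sets distinguished by colour, with the identity line.
#'
#' @param object A `sers_fit` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sers_fit <- function(object, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual_ppm,
                                   y = .data$predicted_ppm,
                                   colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "actual concentration (ppm)",
                  y = "predicted concentration (ppm)",
                  colour = NULL,
                  title = "Calibration: predicted vs actual") +
    ggplot2::theme_minimal()
}

#' Training-history plot
#'
#' @param fit A `sers_fit`.
#' @return A ggplot of per-epoch kernel-Huber training loss (log scale).
#' @export
plot_history <- function(fit) {
  ggplot2::ggplot(fit$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "kernel-Huber training loss") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
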