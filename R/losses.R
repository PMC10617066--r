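#' Huber loss
#'
#' Elementwise robust loss: quadratic `r^2 / 2` for residuals within the
#' truncation tolerance `delta`, linear `delta |r| - delta^2 / 2` beyond it,
#' with `r = y - yhat`. The two branches agree at `|r| = delta`.
#'
#' @param y,yhat Equal-length numeric vectors of targets and predictions.
#' @param delta Truncation tolerance `> 0`.
#' @return Per-sample loss vector.
#' @examples
#' huber(0.5, 0, delta = 1)  # 0.125
#' huber(2, 0, delta = 1)    # 1.5
#' @export
huber <- function(y, yhat, delta = 1) {
  if (length(y) != length(yhat)) stop_shape("y and yhat must have equal length")
  if (!is.finite(delta) || delta <= 0) stop_value("delta must be > 0")
  r <- y - yhat
  quad <- abs(r) <= delta
  out <- numeric(length(r))
  out[quad] <- 0.5 * r[quad]^2
  out[!quad] <- delta * abs(r[!quad]) - 0.5 * delta^2
  out
}

#' Gaussian kernel weight
#'
#' `exp(-(u - v)^2 / (2 sigma^2))`, a similarity in `(0, 1]`, symmetric in
#' its arguments.
#'
#' @param u,v Numeric vectors (recycled elementwise).
#' @param sigma Kernel bandwidth `> 0`.
#' @return Weights in `(0, 1]`.
#' @export
gaussian_kernel <- function(u, v, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop_value("sigma must be > 0")
  exp(-((u - v)^2) / (2 * sigma^2))
}

#' Median-heuristic kernel bandwidth
#'
#' The default bandwidth for the kernel-Huber loss: the median absolute
#' pairwise difference `median |y_i - y_j|` (over `i < j`) of the training
#' targets, a standard scale heuristic for Gaussian kernels. Falls back to 1
#' when the targets are all equal.
#'
#' @param y Numeric vector of (scaled) training targets.
#' @return A positive bandwidth.
#' @export
sigma_heuristic <- function(y) {
  if (length(y) < 2) return(1)
  d <- abs(as.vector(stats::dist(matrix(y, ncol = 1))))
  med <- stats::median(d)
  if (!is.finite(med) || med <= 0) 1 else med
}

resolve_sigma <- function(sigma, y) {
  if (identical(sigma, "auto") || is.null(sigma)) sigma_heuristic(y) else sigma
}

kernel_weights <- function(y, yhat, sigma) {
  k <- exp(-(outer(y, yhat, "-")^2) / (2 * sigma^2))
  rowSums(k)
}

#' Kernel-Huber loss
#'
#' The package's robust training loss: per-sample Huber terms weighted by
#' Gaussian-kernel similarities between targets and the prediction vector,
#' `L = sum_i w_i L_delta(y_i, yhat_i) / sum_i w_i` with
#' `w_i = sum_j K(y_i, yhat_j)`. Samples whose target is far from every
#' prediction (outliers) receive small kernel weight, so they pull on the fit
#' less than under a plain mean; as `sigma -> Inf` all weights tend to 1 and
#' the loss reduces to the unweighted mean Huber loss.
#'
#' @param y,yhat Equal-length numeric vectors (length >= 1).
#' @param delta Huber truncation tolerance `> 0` (target-scale units).
#' @param sigma Kernel bandwidth `> 0`, or `"auto"` for the
#'   [median heuristic][sigma_heuristic] computed on `y`.
#' @return A single finite non-negative loss value.
#' @examples
#' kernel_huber(c(0, 1), c(0, 2), delta = 1, sigma = 1)  # ~0.25827
#' @export
kernel_huber <- function(y, yhat, delta = 1, sigma = "auto") {
  if (length(y) == 0) stop_value("empty target vector")
  if (length(y) != length(yhat)) stop_shape("y and yhat must have equal length")
  sigma <- resolve_sigma(sigma, y)
  if (!is.finite(sigma) || sigma <= 0) stop_value("sigma must be > 0")
  w <- kernel_weights(y, yhat, sigma)
  sum(w * huber(y, yhat, delta)) / sum(w)
}

#' Gradient of the kernel-Huber loss with respect to predictions
#'
#' Analytic gradient used by the training loop. With `detach_weights = TRUE`
#' (the default, and the behaviour used during network training) the kernel
#' weights `w_i` are treated as constants of the current batch, giving
#' `dL/dyhat_i = -w_i psi_delta(r_i) / sum(w)` where
#' `psi_delta(r) = clip(r, -delta, delta)` is the Huber influence function.
#' With `detach_weights = FALSE` the gradient additionally flows through the
#' Gaussian kernel terms.
#'
#' @inheritParams kernel_huber
#' @param detach_weights Treat the kernel weights as constants (default
#'   `TRUE`).
#' @return Gradient vector `dL/dyhat`, same length as `yhat`.
#' @export
kernel_huber_grad <- function(y, yhat, delta = 1, sigma = "auto",
                              detach_weights = TRUE) {
  if (length(y) == 0) stop_value("empty target vector")
  if (length(y) != length(yhat)) stop_shape("y and yhat must have equal length")
  sigma <- resolve_sigma(sigma, y)
  if (!is.finite(sigma) || sigma <= 0) stop_value("sigma must be > 0")
  r <- y - yhat
  psi <- pmin(pmax(r, -delta), delta)
  k <- exp(-(outer(y, yhat, "-")^2) / (2 * sigma^2))
  w <- rowSums(k)
  sw <- sum(w)
  detached <- -(w * psi) / sw
  if (detach_weights) return(detached)
  h <- huber(y, yhat, delta)
  # dK(y_i, yhat_m)/dyhat_m = K * (y_i - yhat_m) / sigma^2
  dk <- k * outer(y, yhat, "-") / sigma^2   # n x n, entry (i, m)
  sl <- sum(w * h)
  # quotient rule: L = SL / SW with SL = sum_i w_i h_i, SW = sum_i w_i
  dsl <- detached * sw + colSums(dk * h)    # first term is w_m * dh_m/dyhat_m
  dsw <- colSums(dk)
  (dsl * sw - sl * dsw) / sw^2
}

#' Plain losses for ablation
#'
#' Mean squared error and mean absolute error, provided so the robust loss
#' can be compared against standard choices.
#'
#' @inheritParams huber
#' @return A single numeric value.
#' @export
mse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_shape("y and yhat must have equal length")
  mean((y - yhat)^2)
}

#' @rdname mse
#' @export
mae <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_shape("y and yhat must have equal length")
  mean(abs(y - yhat))
}
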