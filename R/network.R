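#' Depthwise, pointwise and separable 1D convolutions
#'
#' The building blocks of the separable convolutional regressor, exposed as
#' plain matrix operations for inspection and testing. Inputs are
#' channels-by-length matrices; all convolutions use 'same' zero padding and
#' stride 1, so the signal length is preserved.
#'
#' * `depthwise_conv1d()` filters each channel with its own kernel and never
#'   mixes channels.
#' * `pointwise_conv1d()` applies a position-wise linear map across channels
#'   (a 1x1 convolution).
#' * `separable_conv1d()` is their composition -- the factorised replacement
#'   for a standard convolution, using `D_k M + M N` weights where the
#'   standard layer needs `D_k M N`.
#'
#' @param x Numeric matrix `[channels x length]`.
#' @param kernels Matrix `[channels x D_k]`, one odd-length kernel per
#'   channel.
#' @param weights Matrix `[out_channels x in_channels]`.
#' @param bias Optional per-output-channel bias vector.
#' @return A numeric matrix (`[channels x length]` for depthwise,
#'   `[out_channels x length]` otherwise).
#' @examples
#' x <- matrix(rnorm(12), nrow = 3)
#' depthwise_conv1d(x, matrix(c(0, 1, 0), 3, 3, byrow = TRUE))  # identity
#' @export
depthwise_conv1d <- function(x, kernels) {
  x <- as.matrix(x)
  kernels <- as.matrix(kernels)
  if (nrow(kernels) != nrow(x)) {
    stop_shape("need exactly one kernel per input channel")
  }
  if (ncol(kernels) %% 2 == 0) stop_shape("kernel size must be odd")
  out <- dw_forward(x, kernels, ncol(x), 1L)
  matrix(out, nrow(x), ncol(x))
}

#' @rdname depthwise_conv1d
#' @export
pointwise_conv1d <- function(x, weights, bias = NULL) {
  x <- as.matrix(x)
  weights <- as.matrix(weights)
  if (ncol(weights) != nrow(x)) {
    stop_shape("ncol(weights) must equal the input channel count")
  }
  out <- weights %*% x
  if (!is.null(bias)) {
    if (length(bias) != nrow(weights)) stop_shape("one bias per output channel")
    out <- out + bias
  }
  out
}

#' @rdname depthwise_conv1d
#' @export
separable_conv1d <- function(x, kernels, weights, bias = NULL) {
  pointwise_conv1d(depthwise_conv1d(x, kernels), weights, bias)
}

#' Parameter-cost ratio of separable vs standard convolution
#'
#' The weight-count ratio `(D_k M + M N) / (D_k M N) = 1/N + 1/D_k` of a
#' depthwise separable convolution relative to the standard convolution with
#' the same kernel size and channel counts; for many output channels the
#' saving approaches a factor `D_k`.
#'
#' @param d_k Kernel size `>= 1`.
#' @param n_out Output channel count `>= 1`.
#' @return The ratio `1/n_out + 1/d_k`.
#' @examples
#' cost_ratio(3, 8)  # 11/24
#' @export
cost_ratio <- function(d_k, n_out) {
  if (d_k < 1 || n_out < 1) stop_value("d_k and n_out must be >= 1")
  1 / n_out + 1 / d_k
}

#' @rdname cost_ratio
#' @param m_in Input channel count.
#' @export
separable_param_count <- function(d_k, m_in, n_out) d_k * m_in + m_in * n_out

#' @rdname cost_ratio
#' @export
standard_param_count <- function(d_k, m_in, n_out) d_k * m_in * n_out

# ---------------------------------------------------------------------------
# batched internals. The convolution loops live in src/conv.cpp; the 1x1
# (pointwise) map is a plain GEMM and stays in R. Activations are stored as
# plain [channels x (length * samples)] matrices; every kernel takes the
# length L and batch size n explicitly, so no reshape copies are needed
# between layers.

dw_forward <- function(x, w, L, n) {
  dw_fwd_cpp(x, w, nrow(x), L, n)
}

dw_backward <- function(x, w, dy, L, n) {
  dw_bwd_cpp(x, w, dy, nrow(x), L, n)
}

pw_forward <- function(x, w, b) {
  w %*% x + b
}

pw_backward <- function(x, w, dy) {
  list(
    dx = crossprod(w, dy),
    dw = tcrossprod(dy, x),
    db = rowSums(dy)
  )
}

conv_forward <- function(x, w, b, L, n) {
  # standard conv: w is [n_out, m_in, d_k]
  dw <- dim(w)
  conv_fwd_cpp(x, as.vector(w), b, nrow(x), L, n, dw[1], dw[3])
}

conv_backward <- function(x, w, dy, L, n) {
  dw <- dim(w)
  conv_bwd_cpp(x, as.vector(w), dy, nrow(x), L, n, dw[1], dw[3])
}

relu <- function(x) relu_fwd_cpp(x)

gap_forward <- function(x, L, n) {
  gap_fwd_cpp(x, nrow(x), L, n)
}

gap_backward <- function(df, L) {
  gap_bwd_cpp(df, L)
}

# ---------------------------------------------------------------------------
# model configuration and parameter bookkeeping

#' Configure the residual separable CNN regressor
#'
#' The default architecture is deliberately small: a standard convolution
#' stem, two residual blocks of depthwise separable convolutions, a global
#' average pool, and a dense head ending in one concentration output --
#' under ten thousand weights, so a genetic search over the full flattened
#' weight vector stays tractable. Each block computes
#' `separable conv -> ReLU -> separable conv`, adds the skip path (a 1x1
#' projection when the channel counts differ, identity otherwise), and the
#' model applies a ReLU between stages.
#'
#' @param input_length Number of spectral channels fed to the network.
#' @param stem_channels,stem_kernel Standard-conv stem width and (odd)
#'   kernel size.
#' @param block_channels,block_kernel Channel width and (odd) kernel size of
#'   each residual block; vectors give per-block values, `n_blocks = 0`
#'   drops the blocks entirely (stem + head only).
#' @param n_blocks Number of residual blocks.
#' @param hidden Width of the dense layer after pooling.
#' @param seed Seed for the fan-in-scaled uniform weight initialisation.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(input_length, stem_channels = 8, stem_kernel = 7,
                       block_channels = 16, block_kernel = 5, n_blocks = 2,
                       hidden = 16, seed = 1L) {
  if (input_length < 1) stop_config("input_length must be >= 1")
  if (n_blocks < 0) stop_config("n_blocks must be >= 0")
  block_channels <- rep_len(block_channels, max(n_blocks, 1))[seq_len(n_blocks)]
  block_kernel <- rep_len(block_kernel, max(n_blocks, 1))[seq_len(n_blocks)]
  ok_odd <- function(k) all(k %% 2 == 1) && all(k >= 1)
  if (!ok_odd(stem_kernel) || (n_blocks > 0 && !ok_odd(block_kernel))) {
    stop_config("kernel sizes must be odd and >= 1 ('same' padding)")
  }
  if (stem_channels < 1 || hidden < 1 ||
      (n_blocks > 0 && any(block_channels < 1))) {
    stop_config("channel and hidden widths must be >= 1")
  }
  structure(
    list(input_length = as.integer(input_length),
         stem_channels = as.integer(stem_channels),
         stem_kernel = as.integer(stem_kernel),
         block_channels = as.integer(block_channels),
         block_kernel = as.integer(block_kernel),
         n_blocks = as.integer(n_blocks),
         hidden = as.integer(hidden),
         seed = as.integer(seed)),
    class = "cnn_config"
  )
}

param_shapes <- function(cfg) {
  shapes <- list(
    stem_w = c(cfg$stem_channels, 1L, cfg$stem_kernel),
    stem_b = cfg$stem_channels
  )
  in_ch <- cfg$stem_channels
  for (b in seq_len(cfg$n_blocks)) {
    out_ch <- cfg$block_channels[b]
    k <- cfg$block_kernel[b]
    pre <- sprintf("b%d_", b)
    shapes[[paste0(pre, "dw1")]] <- c(in_ch, k)
    shapes[[paste0(pre, "pw1")]] <- c(out_ch, in_ch)
    shapes[[paste0(pre, "pb1")]] <- out_ch
    shapes[[paste0(pre, "dw2")]] <- c(out_ch, k)
    shapes[[paste0(pre, "pw2")]] <- c(out_ch, out_ch)
    shapes[[paste0(pre, "pb2")]] <- out_ch
    if (in_ch != out_ch) {
      shapes[[paste0(pre, "proj_w")]] <- c(out_ch, in_ch)
      shapes[[paste0(pre, "proj_b")]] <- out_ch
    }
    in_ch <- out_ch
  }
  shapes$head1_w <- c(cfg$hidden, in_ch)
  shapes$head1_b <- cfg$hidden
  shapes$head2_w <- c(1L, cfg$hidden)
  shapes$head2_b <- 1L
  shapes
}

#' Analytic parameter count of a network configuration
#'
#' @param cfg A [cnn_config()].
#' @return Total number of trainable weights.
#' @export
count_params <- function(cfg) {
  sum(vapply(param_shapes(cfg), prod, numeric(1)))
}

init_param <- function(shape) {
  # fan-in scaled uniform: U(-sqrt(3/fan_in), sqrt(3/fan_in)); biases at zero
  n <- prod(shape)
  if (length(shape) == 1) return(numeric(shape))
  fan_in <- prod(shape[-1])
  lim <- sqrt(3 / fan_in)
  vals <- stats::runif(n, -lim, lim)
  if (length(shape) == 2) matrix(vals, shape[1], shape[2]) else array(vals, shape)
}

#' Build a separable CNN regressor
#'
#' Instantiates the parameter tensors of a [cnn_config()] with a seeded
#' fan-in-scaled uniform initialisation (biases start at zero).
#'
#' @param cfg A [cnn_config()].
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A `sers_cnn` model object.
#' @export
build_model <- function(cfg, seed = NULL) {
  if (!inherits(cfg, "cnn_config")) stop_config("cfg must be a cnn_config")
  shapes <- param_shapes(cfg)
  params <- with_seed(if (is.null(seed)) cfg$seed else seed,
                      lapply(shapes, init_param))
  model <- structure(list(config = cfg, params = params), class = "sers_cnn")
  stopifnot(length(flatten_weights(model)) == count_params(cfg))
  model
}

#' @export
print.sers_cnn <- function(x, ...) {
  cfg <- x$config
  cat("<sers_cnn> separable residual CNN regressor\n")
  cat("  input channels:", cfg$input_length, "\n")
  cat("  stem:", cfg$stem_channels, "ch, kernel", cfg$stem_kernel, "\n")
  if (cfg$n_blocks > 0) {
    cat("  blocks:", cfg$n_blocks, "x separable (",
        paste(cfg$block_channels, collapse = "/"), "ch, kernel",
        paste(cfg$block_kernel, collapse = "/"), ")\n")
  }
  cat("  head: GAP -> dense(", cfg$hidden, ") -> 1\n", sep = "")
  cat("  parameters:", count_params(cfg), "\n")
  invisible(x)
}

new_workspace <- function(cfg, n) {
  cnn_ws_new(cfg$input_length, as.integer(n), cfg$stem_channels,
             cfg$stem_kernel, cfg$block_channels, cfg$block_kernel,
             cfg$hidden)
}

# forward pass; returns predictions and (optionally) the cache needed by
# backprop. x is a [1 x (L * n)] matrix of n stacked length-L spectra. The
# cache is an external-pointer workspace holding all intermediate
# activations; passing a preallocated `ws` makes repeated calls
# allocation-free.
model_forward <- function(params, cfg, x, keep_cache = FALSE, ws = NULL) {
  L <- cfg$input_length
  n <- ncol(x) / L
  if (is.null(ws)) ws <- new_workspace(cfg, n)
  yhat <- cnn_forward_ws(ws, params, x)
  if (keep_cache) list(yhat = yhat, cache = ws) else list(yhat = yhat)
}

model_forward_r <- function(params, cfg, x, keep_cache = FALSE) {
  L <- cfg$input_length
  n <- ncol(x) / L
  cache <- list(x = x, L = L, n = n)
  z <- conv_forward(x, params$stem_w, params$stem_b, L, n)
  cache$stem_z <- z
  h <- relu(z)
  in_ch <- cfg$stem_channels
  for (b in seq_len(cfg$n_blocks)) {
    pre <- sprintf("b%d_", b)
    out_ch <- cfg$block_channels[b]
    c1 <- list(h_in = h)
    c1$t1 <- dw_forward(h, params[[paste0(pre, "dw1")]], L, n)
    c1$u1 <- pw_forward(c1$t1, params[[paste0(pre, "pw1")]],
                        params[[paste0(pre, "pb1")]])
    c1$a1 <- relu(c1$u1)
    c1$t2 <- dw_forward(c1$a1, params[[paste0(pre, "dw2")]], L, n)
    u2 <- pw_forward(c1$t2, params[[paste0(pre, "pw2")]],
                     params[[paste0(pre, "pb2")]])
    if (in_ch != out_ch) {
      skip <- pw_forward(h, params[[paste0(pre, "proj_w")]],
                         params[[paste0(pre, "proj_b")]])
    } else {
      skip <- h
    }
    c1$res <- u2 + skip
    h <- relu(c1$res)
    if (keep_cache) cache[[paste0(pre, "cache")]] <- c1
    in_ch <- out_ch
  }
  cache$trunk_out <- h
  f <- gap_forward(h, L, n)
  cache$f <- f
  g_z <- params$head1_w %*% f + params$head1_b
  cache$g_z <- g_z
  g <- relu(g_z)
  cache$g <- g
  yhat <- as.vector(params$head2_w %*% g + params$head2_b)
  if (keep_cache) list(yhat = yhat, cache = cache) else list(yhat = yhat)
}

# backward pass: dyhat is dL/dyhat (length n); returns gradients for every
# parameter tensor, same shapes as params. `cache` is the workspace filled
# by the preceding model_forward(..., keep_cache = TRUE).
model_backward <- function(params, cfg, cache, dyhat) {
  grads <- cnn_backward_ws(cache, params, as.double(dyhat))
  grads[names(params)]
}

model_backward_r <- function(params, cfg, cache, dyhat) {
  grads <- list()
  n <- length(dyhat)
  L <- cache$L
  dyrow <- matrix(dyhat, 1, n)
  grads$head2_w <- dyrow %*% t(cache$g)
  grads$head2_b <- sum(dyhat)
  dg <- relu_bwd_cpp(crossprod(params$head2_w, dyrow), cache$g_z)
  grads$head1_w <- dg %*% t(cache$f)
  grads$head1_b <- rowSums(dg)
  df <- crossprod(params$head1_w, dg)
  dh <- gap_backward(df, L)
  in_chs <- c(cfg$stem_channels, cfg$block_channels)
  for (b in rev(seq_len(cfg$n_blocks))) {
    pre <- sprintf("b%d_", b)
    c1 <- cache[[paste0(pre, "cache")]]
    in_ch <- in_chs[b]
    out_ch <- cfg$block_channels[b]
    dres <- relu_bwd_cpp(dh, c1$res)
    # branch: pw2 <- dw2 <- relu <- pw1 <- dw1
    bw2 <- pw_backward(c1$t2, params[[paste0(pre, "pw2")]], dres)
    grads[[paste0(pre, "pw2")]] <- bw2$dw
    grads[[paste0(pre, "pb2")]] <- bw2$db
    bdw2 <- dw_backward(c1$a1, params[[paste0(pre, "dw2")]], bw2$dx, L, n)
    grads[[paste0(pre, "dw2")]] <- bdw2$dw
    da1 <- relu_bwd_cpp(bdw2$dx, c1$u1)
    bw1 <- pw_backward(c1$t1, params[[paste0(pre, "pw1")]], da1)
    grads[[paste0(pre, "pw1")]] <- bw1$dw
    grads[[paste0(pre, "pb1")]] <- bw1$db
    bdw1 <- dw_backward(c1$h_in, params[[paste0(pre, "dw1")]], bw1$dx, L, n)
    grads[[paste0(pre, "dw1")]] <- bdw1$dw
    dh_in <- bdw1$dx
    # skip path
    if (in_ch != out_ch) {
      bp <- pw_backward(c1$h_in, params[[paste0(pre, "proj_w")]], dres)
      grads[[paste0(pre, "proj_w")]] <- bp$dw
      grads[[paste0(pre, "proj_b")]] <- bp$db
      dh_in <- dh_in + bp$dx
    } else {
      dh_in <- dh_in + dres
    }
    dh <- dh_in
  }
  dh <- relu_bwd_cpp(dh, cache$stem_z)
  bst <- conv_backward(cache$x, params$stem_w, dh, L, n)
  grads$stem_w <- bst$dw
  grads$stem_b <- bst$db
  grads[names(params)]
}

#' Residual block forward map
#'
#' Applies one residual unit, `F(x) + skip(x)`, where the branch `F` is
#' `separable conv -> ReLU -> separable conv` and the skip path is the
#' identity (equal channel counts) or a 1x1 projection. With all branch (and
#' projection-free) weights at zero the block is exactly the identity map,
#' which is also why gradient flows to the input even when the branch
#' saturates.
#'
#' @param x Input matrix `[channels x length]`.
#' @param block Named list of parameter matrices: `dw1`, `pw1`, `pb1`,
#'   `dw2`, `pw2`, `pb2`, and optionally `proj_w`, `proj_b`.
#' @return Output matrix `[out_channels x length]`.
#' @export
residual_block <- function(x, block) {
  x <- as.matrix(x)
  branch <- depthwise_conv1d(x, block$dw1)
  branch <- pointwise_conv1d(branch, block$pw1, block$pb1)
  branch <- relu(branch)
  branch <- depthwise_conv1d(branch, block$dw2)
  branch <- pointwise_conv1d(branch, block$pw2, block$pb2)
  skip <- if (!is.null(block$proj_w)) {
    pointwise_conv1d(x, block$proj_w, block$proj_b)
  } else {
    if (nrow(block$pw2) != nrow(x)) {
      stop_shape("skip and branch shapes differ; provide a projection")
    }
    x
  }
  branch + skip
}

spectra_to_input <- function(x) {
  m <- if (is.matrix(x)) x else spectra_matrix(as_spectra(x))
  matrix(t(m), nrow = 1)
}

#' Predict concentrations with a fitted (or raw) model
#'
#' Runs the deterministic forward pass. Predictions come out on the scaled
#' target axis; pass a `scaler` to report ppm.
#'
#' @param object A `sers_cnn` model.
#' @param newdata A [spectra_tbl][as_spectra] or samples-by-channels matrix
#'   whose channel count matches the model's `input_length`.
#' @param scaler Optional [fit_scaler()] result; when given, predictions are
#'   inverse-transformed to ppm.
#' @param ... Unused.
#' @return Numeric vector, one prediction per sample.
#' @export
predict.sers_cnn <- function(object, newdata, scaler = NULL, ...) {
  m <- if (is.matrix(newdata)) newdata else spectra_matrix(as_spectra(newdata))
  if (ncol(m) != object$config$input_length) {
    stop_shape(sprintf("model expects %d channels, data has %d",
                       object$config$input_length, ncol(m)))
  }
  xa <- spectra_to_input(m)
  yhat <- model_forward(object$params, object$config, xa)$yhat
  if (!is.null(scaler)) yhat <- scale_concentration(yhat, scaler, invert = TRUE)
  yhat
}

# ---------------------------------------------------------------------------
# training

#' Train the network under the kernel-Huber loss
#'
#' Full-batch Adam on the hand-derived backpropagation gradients, with the
#' kernel-Huber loss (kernel weights detached per batch by default). When an
#' `init` chromosome is given -- typically the best individual of
#' [run_ga()] -- its weights are loaded before the first gradient step.
#'
#' @param model A `sers_cnn` from [build_model()].
#' @param x Samples-by-channels matrix of scaled intensities (or a
#'   `spectra_tbl`).
#' @param y Scaled targets, one per sample.
#' @param delta,sigma,detach_weights Kernel-Huber parameters (see
#'   [kernel_huber()]); `sigma = "auto"` resolves the median heuristic on
#'   `y` once, before training.
#' @param lr Adam learning rate (the peak rate under the cosine schedule).
#' @param epochs Number of full-batch epochs.
#' @param lr_schedule `"constant"` (default) holds `lr` fixed; `"cosine"`
#'   anneals the rate from `lr` to near zero over the run.
#' @param weight_decay Decoupled weight decay coefficient (per-epoch shrink
#'   `lr * weight_decay * w` applied after the Adam step). With only a few
#'   dozen calibration spectra this is the main guard against unstable
#'   extrapolation just outside the training range; `0` disables it.
#' @param augment_sd Standard deviation of fresh Gaussian noise added to the
#'   (scaled) input features at every epoch -- a scalar, or one value per
#'   channel. Emulating the detector noise during training stops the network
#'   from memorising the one noise realisation of each calibration spectrum,
#'   which is what otherwise limits accuracy at the bottom of the
#'   concentration gradient. `0` disables augmentation.
#' @param seed Seed for the augmentation noise (ignored when
#'   `augment_sd = 0`).
#' @param average_tail Fraction (in `[0, 1)`) of the final epochs whose
#'   weights are averaged into the returned model (stochastic weight
#'   averaging). Averaging the tail of a noisy constant-rate trajectory
#'   cancels much of the epoch-to-epoch wander and typically generalises
#'   better than the last iterate; `0` returns the final weights.
#' @param init Optional flat weight vector to load first (length must equal
#'   the model's parameter count).
#' @return A list with the trained `model` and a `history` tibble
#'   (`epoch`, `loss`).
#' @export
train_network <- function(model, x, y, delta = 1, sigma = "auto",
                          detach_weights = TRUE, lr = 1e-3, epochs = 300,
                          lr_schedule = c("constant", "cosine"),
                          weight_decay = 0, augment_sd = 0, seed = 0L,
                          average_tail = 0, init = NULL) {
  lr_schedule <- match.arg(lr_schedule)
  xa <- spectra_to_input(x)
  n <- ncol(xa) / model$config$input_length
  if (length(y) != n) stop_shape("one target per sample required")
  if (!is.null(init)) {
    if (length(init) != count_params(model$config)) {
      stop_shape("init chromosome length must equal the parameter count")
    }
    model <- unflatten_weights(init, model)
  }
  sigma <- resolve_sigma(sigma, y)
  params <- model$params
  ws <- new_workspace(model$config, n)
  flat <- unlist(params, use.names = FALSE)
  m1 <- numeric(length(flat))
  m2 <- numeric(length(flat))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  losses <- numeric(epochs)
  L <- model$config$input_length
  augment <- any(augment_sd > 0)
  if (augment && !(length(augment_sd) %in% c(1L, L))) {
    stop_shape("augment_sd must be a scalar or one value per channel")
  }
  aug_vec <- if (augment) rep(rep_len(as.double(augment_sd), L), n) else NULL
  if (average_tail < 0 || average_tail >= 1) {
    stop_value("average_tail must be in [0, 1)")
  }
  avg_from <- if (average_tail > 0) {
    as.integer(ceiling(epochs * (1 - average_tail))) } else { epochs + 1L }
  avg_sum <- numeric(length(flat))
  avg_n <- 0L
  run_epochs <- function() {
  for (ep in seq_len(epochs)) {
    x_ep <- if (augment) {
      xa + matrix(stats::rnorm(length(xa), sd = aug_vec), nrow = 1)
    } else {
      xa
    }
    fw <- model_forward(params, model$config, x_ep, keep_cache = TRUE, ws = ws)
    loss <- kernel_huber(y, fw$yhat, delta = delta, sigma = sigma)
    if (!is.finite(loss)) {
      rlang::abort(sprintf("training diverged (non-finite loss at epoch %d)", ep),
                   class = c("sersquant_divergence_error", "sersquant_error"))
    }
    dyhat <- kernel_huber_grad(y, fw$yhat, delta = delta, sigma = sigma,
                               detach_weights = detach_weights)
    grads <- model_backward(params, model$config, fw$cache, dyhat)
    g <- unlist(grads, use.names = FALSE)
    m1 <- beta1 * m1 + (1 - beta1) * g
    m2 <- beta2 * m2 + (1 - beta2) * g^2
    lr_ep <- if (lr_schedule == "cosine") {
      lr * 0.5 * (1 + cos(pi * (ep - 1) / max(epochs - 1, 1)))
    } else {
      lr
    }
    step <- lr_ep * (m1 / (1 - beta1^ep)) / (sqrt(m2 / (1 - beta2^ep)) + eps)
    flat <- unlist(params, use.names = FALSE)
    flat <- flat - step - lr_ep * weight_decay * flat
    params <<- relist_params(flat, params)
    losses[ep] <<- loss
    if (ep >= avg_from) {
      avg_sum <<- avg_sum + flat
      avg_n <<- avg_n + 1L
    }
  }
  invisible(NULL)
  }
  if (augment) with_seed(seed, run_epochs()) else run_epochs()
  if (avg_n > 0) params <- relist_params(avg_sum / avg_n, params)
  model$params <- params
  list(model = model,
       history = tibble::tibble(epoch = seq_len(epochs), loss = losses))
}

relist_params <- function(flat, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    v <- flat[pos + seq_len(n)]
    if (is.null(dim(template[[nm]]))) {
      out[[nm]] <- v
    } else {
      out[[nm]] <- array(v, dim(template[[nm]]))
    }
    pos <- pos + n
  }
  out
}
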