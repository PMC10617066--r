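# Brute-force reference implementations used as independent oracles.
# These deliberately use nothing from the package's compute path.

# direct triple-loop depthwise convolution, 'same' zero padding
brute_depthwise <- function(x, w) {
  M <- nrow(x); L <- ncol(x); dk <- ncol(w); p <- (dk - 1) / 2
  out <- matrix(0, M, L)
  for (c in seq_len(M)) {
    for (t in seq_len(L)) {
      for (k in seq_len(dk)) {
        s <- t + k - p - 1
        if (s >= 1 && s <= L) out[c, t] <- out[c, t] + w[c, k] * x[c, s]
      }
    }
  }
  out
}

# direct per-position matrix multiply (1x1 convolution)
brute_pointwise <- function(x, w, b = NULL) {
  N <- nrow(w); L <- ncol(x)
  out <- matrix(0, N, L)
  for (t in seq_len(L)) {
    out[, t] <- w %*% x[, t]
    if (!is.null(b)) out[, t] <- out[, t] + b
  }
  out
}

# dense direct solve of the Whittaker system (W + lam D'D) z = W y
brute_whittaker <- function(y, w, lam) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  solve(diag(w, n) + lam * t(D) %*% D, w * y)
}

# double-loop evaluation of the kernel-weighted robust loss
brute_kernel_huber <- function(y, yhat, delta, sigma) {
  n <- length(y)
  hub <- function(r) if (abs(r) <= delta) 0.5 * r^2 else delta * abs(r) - 0.5 * delta^2
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      k <- exp(-((y[i] - yhat[j])^2) / (2 * sigma^2))
      num <- num + k * hub(y[i] - yhat[i])
      den <- den + k
    }
  }
  num / den
}

# central finite differences of f at x
fd_gradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    p <- x; m <- x
    p[i] <- p[i] + eps
    m[i] <- m[i] - eps
    (f(p) - f(m)) / (2 * eps)
  }, numeric(1))
}

# small labeled spectra table for container tests
tiny_spectra <- function(n_samples = 3, L = 10) {
  axis <- seq(100, by = 5, length.out = L)
  m <- outer(seq_len(n_samples), seq_len(L), function(i, j) i * 10 + j)
  spectra_from_matrix(m, axis,
                      sample_ids = sprintf("T%02d", seq_len(n_samples)),
                      concentrations = seq_len(n_samples) * 1.5)
}

# evaluate expr under a temporary seed without disturbing the session RNG
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
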