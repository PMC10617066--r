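#' Characteristic-peak wavenumber windows
#'
#' A window set is a tibble of closed wavenumber intervals `[lo, hi]` cm^-1,
#' sorted and non-overlapping. The defaults are the two regions where the
#' analyte's strong bands sit, 519-617 and 1292-1713 cm^-1; only channels
#' inside these windows are carried into the regression model.
#'
#' @param lo,hi Numeric vectors of interval bounds (paired).
#' @return A `window_set` tibble with columns `lo`, `hi`.
#' @examples
#' default_windows()
#' window_set(lo = c(400, 900), hi = c(500, 1000))
#' @export
window_set <- function(lo, hi) {
  if (length(lo) != length(hi) || length(lo) == 0) {
    stop_config("lo and hi must be non-empty paired vectors")
  }
  w <- tibble::tibble(lo = as.double(lo), hi = as.double(hi))
  w <- w[order(w$lo), , drop = FALSE]
  if (any(w$lo >= w$hi)) stop_config("each window needs lo < hi")
  if (nrow(w) > 1 && any(w$lo[-1] <= w$hi[-nrow(w)])) {
    stop_config("windows must not overlap")
  }
  class(w) <- c("window_set", class(tibble::tibble()))
  w
}

#' @rdname window_set
#' @export
default_windows <- function() window_set(lo = c(519, 1292), hi = c(617, 1713))

#' Restrict spectra to characteristic windows
#'
#' Keeps exactly the channels whose wavenumber falls inside any closed
#' interval of the window set, concatenated in axis order. Membership is by
#' wavenumber value, not channel index, and the operation is idempotent.
#'
#' @param x A [spectra_tbl][as_spectra].
#' @param windows A [window_set()] (default [default_windows()]).
#' @return A `spectra_tbl` on the reduced axis.
#' @export
select_windows <- function(x, windows = default_windows()) {
  x <- as_spectra(x)
  if (!inherits(windows, "window_set")) windows <- window_set(windows$lo, windows$hi)
  axis <- spectra_axis(x)
  keep_axis <- rep(FALSE, length(axis))
  for (k in seq_len(nrow(windows))) {
    keep_axis <- keep_axis | (axis >= windows$lo[k] & axis <= windows$hi[k])
  }
  if (!any(keep_axis)) {
    rlang::abort("no spectral channels fall inside the requested windows",
                 class = c("sersquant_selection_error", "sersquant_error"))
  }
  out <- x[x$wavenumber %in% axis[keep_axis], , drop = FALSE]
  as_spectra(out)
}

#' Min-max feature scaler fitted on training spectra
#'
#' Fits per-channel min-max scaling to `[0, 1]` on the training set only
#' (constant channels get scale 1 so they map to 0 rather than dividing by
#' zero), and records the concentration divisor that maps ppm targets into
#' `(0, 1]`. Applying the scaler to other datasets uses the training
#' statistics unchanged, so test values outside the training range simply map
#' outside `[0, 1]` -- there is no clipping and no leakage of test statistics.
#'
#' @param train A non-empty labeled [spectra_tbl][as_spectra].
#' @param conc_max Concentration divisor in ppm; defaults to the maximum
#'   training label.
#' @return A `sers_scaler` object.
#' @seealso [scale_spectra()], [scale_concentration()], [scale_features()]
#' @export
fit_scaler <- function(train, conc_max = NULL) {
  train <- as_spectra(train)
  if (nrow(train) == 0) stop_value("training set must be non-empty")
  m <- spectra_matrix(train)
  mins <- apply(m, 2, min)
  maxs <- apply(m, 2, max)
  ranges <- maxs - mins
  ranges[ranges == 0] <- 1
  if (is.null(conc_max)) {
    conc <- spectra_concentrations(train)
    conc <- conc[!is.na(conc)]
    if (length(conc) == 0) stop_value("no labels to derive conc_max from")
    conc_max <- max(conc)
  }
  if (conc_max <= 0) stop_value("conc_max must be > 0")
  structure(
    list(axis = spectra_axis(train), mins = unname(mins),
         ranges = unname(ranges), conc_max = conc_max),
    class = "sers_scaler"
  )
}

#' Apply (or invert) a fitted scaler to spectra
#'
#' @param x A [spectra_tbl][as_spectra] on the scaler's axis.
#' @param scaler A [fit_scaler()] result.
#' @param invert If `TRUE`, undo the scaling instead.
#' @return A `spectra_tbl` of scaled intensities (labels untouched; use
#'   [scale_concentration()] for targets).
#' @export
scale_spectra <- function(x, scaler, invert = FALSE) {
  x <- as_spectra(x)
  axis <- spectra_axis(x)
  if (length(axis) != length(scaler$axis) || any(axis != scaler$axis)) {
    stop_shape("spectra are not on the scaler's wavenumber axis")
  }
  m <- spectra_matrix(x)
  if (invert) {
    m <- sweep(sweep(m, 2, scaler$ranges, "*"), 2, scaler$mins, "+")
  } else {
    m <- sweep(sweep(m, 2, scaler$mins, "-"), 2, scaler$ranges, "/")
  }
  spectra_from_matrix(m, axis, sample_ids = spectra_ids(x),
                      concentrations = unname(spectra_concentrations(x)))
}

#' @rdname scale_spectra
#' @param conc Concentrations in ppm (or scaled units when `invert = TRUE`).
#' @export
scale_concentration <- function(conc, scaler, invert = FALSE) {
  if (invert) conc * scaler$conc_max else conc / scaler$conc_max
}

#' Scale a training set and companion sets together
#'
#' Convenience wrapper matching the usual chemometric workflow: fit the
#' min-max scaler on `train`, apply it to `train` and to every dataset in
#' `...`, and return everything with the scaler state.
#'
#' @param train A labeled [spectra_tbl][as_spectra].
#' @param ... Further `spectra_tbl`s on the same axis (e.g. a test set).
#' @param conc_max Optional ppm divisor passed to [fit_scaler()].
#' @return A list with `train`, one entry per `...` dataset, and `scaler`.
#' @export
scale_features <- function(train, ..., conc_max = NULL) {
  scaler <- fit_scaler(train, conc_max = conc_max)
  others <- lapply(list(...), scale_spectra, scaler = scaler)
  out <- c(list(train = scale_spectra(train, scaler)), others, list(scaler = scaler))
  out
}

#' Train/test split over the concentration gradient
#'
#' Splits a labeled dataset into disjoint, exhaustive train and test sets.
#' The default `"stratified"` method walks the samples in sorted
#' concentration order and sends every `ceiling(n / n_test)`-th one to the
#' test set, so the held-out samples span the whole gradient -- the desk
#' analogue of the 40/11 protocol used for a 51-sample gradient. A purely
#' random split is available with `method = "random"`.
#'
#' @param x A labeled [spectra_tbl][as_spectra].
#' @param n_train Number of training samples, `0 < n_train < n`.
#' @param seed Seed for the random method (ignored by the deterministic
#'   stratified method, but accepted so call sites can stay uniform).
#' @param method `"stratified"` (default) or `"random"`.
#' @return A list with `spectra_tbl`s `train` and `test`.
#' @export
split_spectra <- function(x, n_train = 40, seed = NULL,
                          method = c("stratified", "random")) {
  method <- match.arg(method)
  x <- as_spectra(x)
  ids <- spectra_ids(x)
  n <- length(ids)
  if (n_train <= 0 || n_train >= n) {
    stop_value("n_train must satisfy 0 < n_train < n_samples")
  }
  n_test <- n - n_train
  if (method == "stratified") {
    conc <- spectra_concentrations(x)
    if (any(is.na(conc))) {
      stop_value("stratified split needs concentration labels on every sample")
    }
    ord <- order(conc, seq_len(n))
    step <- ceiling(n / n_test)
    pos <- seq(1, n, by = step)
    if (length(pos) != n_test) {
      # degenerate ratios where the every-k-th walk misses the count:
      # fall back to an evenly spaced rank selection of exactly n_test
      pos <- unique(round(seq(1, n, length.out = n_test)))
    }
    test_ids <- ids[ord[pos]]
  } else {
    test_ids <- with_seed(seed, sample(ids, n_test))
  }
  train_ids <- setdiff(ids, test_ids)
  list(
    train = filter_samples(x, train_ids),
    test = filter_samples(x, test_ids)
  )
}
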