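#' Tidy container for Raman spectra
#'
#' A `spectra_tbl` is a long-format tibble with one row per (sample, channel)
#' pair and columns
#' \describe{
#'   \item{sample_id}{character sample identifier, unique per spectrum}
#'   \item{wavenumber}{Raman shift in cm^-1, a common strictly increasing
#'     axis shared by every sample}
#'   \item{intensity}{scattering intensity in arbitrary units (finite)}
#'   \item{concentration}{analyte concentration in ppm, or `NA` for
#'     unlabeled samples; constant within a sample}
#' }
#' All verbs in the package (`correct_baseline()`, `select_windows()`,
#' `split_spectra()`, ...) take and return this shape so calls chain with the
#' pipe.
#'
#' @param x A data frame with the columns above.
#' @return `as_spectra()` returns a validated `spectra_tbl`;
#'   `is_spectra()` a logical.
#' @examples
#' axis <- seq(100, 110)
#' df <- tibble::tibble(
#'   sample_id = "a", wavenumber = axis,
#'   intensity = exp(-(axis - 105)^2), concentration = 10
#' )
#' sp <- as_spectra(df)
#' spectra_axis(sp)
#' @export
as_spectra <- function(x) {
  if (!is.data.frame(x)) stop_format("spectra must be a data frame")
  x <- tibble::as_tibble(x)
  needed <- c("sample_id", "wavenumber", "intensity")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop_format(paste0(
      "spectra are missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"concentration" %in% names(x)) x$concentration <- NA_real_
  x$sample_id <- as.character(x$sample_id)
  x$wavenumber <- as.double(x$wavenumber)
  x$intensity <- as.double(x$intensity)
  x$concentration <- as.double(x$concentration)
  x <- x[c("sample_id", "wavenumber", "intensity", "concentration")]
  ids <- unique(x$sample_id)
  x <- x[order(match(x$sample_id, ids), x$wavenumber), , drop = FALSE]
  validate_spectra(x)
  class(x) <- c("spectra_tbl", class(tibble::tibble()))
  x
}

#' @rdname as_spectra
#' @export
is_spectra <- function(x) inherits(x, "spectra_tbl")

validate_spectra <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  ids <- unique(x$sample_id)
  split_idx <- split(seq_len(nrow(x)), factor(x$sample_id, levels = ids))
  axis <- x$wavenumber[split_idx[[1]]]
  if (length(axis) < 2) stop_format("each spectrum needs at least 2 channels")
  if (any(diff(axis) <= 0)) {
    stop_format("wavenumber axis must be strictly increasing")
  }
  for (k in seq_along(split_idx)) {
    i <- split_idx[[k]]
    if (length(i) != length(axis) || any(x$wavenumber[i] != axis)) {
      stop_format(paste0(
        "sample '", ids[k], "' is not on the shared wavenumber axis"
      ))
    }
    conc <- unique(x$concentration[i])
    if (length(conc[!is.na(conc)]) > 1) {
      stop_format(paste0("sample '", ids[k], "' has conflicting labels"))
    }
  }
  if (!all(is.finite(x$intensity))) {
    stop_format("intensities must all be finite")
  }
  conc <- x$concentration
  if (any(!is.na(conc) & conc < 0)) {
    stop_format("concentrations must be >= 0 ppm")
  }
  invisible(x)
}

#' Accessors for spectra tables
#'
#' Small helpers that pull the shared wavenumber axis, the sample identifiers
#' (in first-appearance order), the per-sample concentration labels, or the
#' samples-by-channels intensity matrix out of a [spectra_tbl][as_spectra].
#'
#' @param x A `spectra_tbl`.
#' @return `spectra_axis()`: numeric axis; `spectra_ids()`: character vector;
#'   `spectra_concentrations()`: named numeric vector (NA when unlabeled);
#'   `spectra_matrix()`: numeric matrix with one row per sample, columns named
#'   by wavenumber.
#' @export
spectra_axis <- function(x) {
  if (nrow(x) == 0) return(numeric(0))
  x$wavenumber[x$sample_id == x$sample_id[1]]
}

#' @rdname spectra_axis
#' @export
spectra_ids <- function(x) unique(x$sample_id)

#' @rdname spectra_axis
#' @export
spectra_concentrations <- function(x) {
  ids <- spectra_ids(x)
  first <- match(ids, x$sample_id)
  stats::setNames(x$concentration[first], ids)
}

#' @rdname spectra_axis
#' @export
spectra_matrix <- function(x) {
  ids <- spectra_ids(x)
  axis <- spectra_axis(x)
  m <- matrix(x$intensity, nrow = length(ids), ncol = length(axis),
              byrow = TRUE,
              dimnames = list(ids, format(axis, trim = TRUE)))
  m
}

#' Build a spectra table from an intensity matrix
#'
#' Inverse of [spectra_matrix()]: assembles a long [spectra_tbl][as_spectra]
#' from a samples-by-channels matrix, a shared axis and optional labels.
#'
#' @param m Numeric matrix, one row per sample.
#' @param axis Wavenumber axis (cm^-1), length `ncol(m)`, strictly increasing.
#' @param sample_ids Character vector of ids (default `rownames(m)` or
#'   `"S01"..`).
#' @param concentrations Optional numeric vector of ppm labels (NA allowed).
#' @return A `spectra_tbl`.
#' @export
spectra_from_matrix <- function(m, axis, sample_ids = NULL,
                                concentrations = NULL) {
  m <- as.matrix(m)
  if (ncol(m) != length(axis)) {
    stop_shape("ncol(m) must equal length(axis)")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(m)
    if (is.null(sample_ids)) {
      sample_ids <- sprintf("S%02d", seq_len(nrow(m)))
    }
  }
  if (anyDuplicated(sample_ids)) stop_format("sample ids must be unique")
  if (is.null(concentrations)) concentrations <- rep(NA_real_, nrow(m))
  if (length(concentrations) != nrow(m)) {
    stop_shape("one concentration per sample required")
  }
  df <- tibble::tibble(
    sample_id = rep(as.character(sample_ids), each = length(axis)),
    wavenumber = rep(as.double(axis), times = nrow(m)),
    intensity = as.double(t(m)),
    concentration = rep(as.double(concentrations), each = length(axis))
  )
  as_spectra(df)
}

#' Keep a subset of samples
#'
#' @param x A `spectra_tbl`.
#' @param ids Character vector of sample ids to keep (order preserved).
#' @return A `spectra_tbl` with only those samples.
#' @export
filter_samples <- function(x, ids) {
  missing_ids <- setdiff(ids, spectra_ids(x))
  if (length(missing_ids) > 0) {
    stop_key(paste0("unknown sample id(s): ", paste(missing_ids, collapse = ", ")))
  }
  out <- x[x$sample_id %in% ids, , drop = FALSE]
  out <- out[order(match(out$sample_id, ids)), , drop = FALSE]
  as_spectra(out)
}
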