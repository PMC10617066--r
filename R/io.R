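#' Read Raman spectra from a wide CSV
#'
#' Reads the fixed CSV dialect used by the package: a mandatory header row,
#' first column `wavenumber_cm-1`, then one numeric intensity column per
#' sample (column name = sample id). Concentration labels, if any, live in a
#' separate two-column CSV (`sample_id,concentration_ppm`) so the spectral
#' matrix stays purely numeric. Files use `,` separators, `.` decimals and
#' UTF-8.
#'
#' @param path Path to the spectra CSV.
#' @param labels_path Optional path to the labels CSV. Samples absent from it
#'   are left unlabeled (`NA` ppm). Label rows naming a sample id that is not
#'   in the spectra file raise a key error.
#' @return A [spectra_tbl][as_spectra].
#' @seealso [write_spectra_csv()]
#' @export
read_spectra_csv <- function(path, labels_path = NULL) {
  if (!file.exists(path)) stop_value(paste0("file not found: ", path))
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_double()))
  if (ncol(wide) < 1 || names(wide)[1] != "wavenumber_cm-1") {
    stop_format("first CSV column must be named 'wavenumber_cm-1'")
  }
  axis <- wide[["wavenumber_cm-1"]]
  if (any(!is.finite(axis))) stop_format("non-numeric wavenumber axis")
  if (length(axis) >= 2 && any(diff(axis) <= 0)) {
    stop_format("wavenumber axis must be strictly increasing")
  }
  sample_cols <- names(wide)[-1]
  if (length(sample_cols) == 0) {
    out <- as_spectra(tibble::tibble(
      sample_id = character(0), wavenumber = double(0),
      intensity = double(0), concentration = double(0)
    ))
    return(out)
  }
  m <- t(as.matrix(wide[sample_cols]))
  if (any(!is.finite(m))) {
    stop_format("intensity columns contain missing or non-numeric values")
  }
  conc <- rep(NA_real_, length(sample_cols))
  if (!is.null(labels_path)) {
    labels <- read_labels_csv(labels_path)
    unknown <- setdiff(labels$sample_id, sample_cols)
    if (length(unknown) > 0) {
      stop_key(paste0(
        "labels name unknown sample id(s): ", paste(unknown, collapse = ", ")
      ))
    }
    conc[match(labels$sample_id, sample_cols)] <- labels$concentration_ppm
  }
  spectra_from_matrix(m, axis, sample_ids = sample_cols, concentrations = conc)
}

read_labels_csv <- function(path) {
  if (!file.exists(path)) stop_value(paste0("file not found: ", path))
  labels <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                            col_types = readr::cols(
                              sample_id = readr::col_character(),
                              concentration_ppm = readr::col_double()
                            ))
  if (!all(c("sample_id", "concentration_ppm") %in% names(labels))) {
    stop_format("labels CSV needs columns sample_id, concentration_ppm")
  }
  if (anyDuplicated(labels$sample_id)) {
    stop_format("duplicate sample_id in labels CSV")
  }
  labels
}

#' Write Raman spectra to a wide CSV
#'
#' Writes the dialect read by [read_spectra_csv()]; column order follows the
#' sample order of the table. An empty dataset produces a header-only CSV.
#'
#' @param x A [spectra_tbl][as_spectra].
#' @param path Output path for the spectra CSV.
#' @param labels_path Optional output path for the labels CSV; only labeled
#'   samples are written.
#' @return `x`, invisibly.
#' @export
write_spectra_csv <- function(x, path, labels_path = NULL) {
  x <- as_spectra(x)
  if (nrow(x) == 0) {
    writeLines("wavenumber_cm-1", con = path)
  } else {
    m <- spectra_matrix(x)
    wide <- tibble::as_tibble(as.data.frame(t(m), check.names = FALSE))
    wide <- tibble::add_column(wide, `wavenumber_cm-1` = spectra_axis(x),
                               .before = 1)
    readr::write_csv(wide, path, progress = FALSE)
  }
  if (!is.null(labels_path)) {
    conc <- spectra_concentrations(x)
    labels <- tibble::tibble(
      sample_id = names(conc), concentration_ppm = unname(conc)
    )
    labels <- labels[!is.na(labels$concentration_ppm), , drop = FALSE]
    readr::write_csv(labels, labels_path, progress = FALSE)
  }
  invisible(x)
}
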