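#' Configuration for the synthetic SERS spectrum generator
#'
#' Describes a simulated surface-enhanced Raman (SERS) acquisition of a
#' fluoroquinolone-like analyte over a concentration gradient. The generator
#' emulates the structure of a portable-spectrometer ofloxacin measurement:
#' a 239-2400 cm^-1 axis, characteristic peak clusters inside the
#' 519-617 and 1292-1713 cm^-1 windows, a smooth fluorescence baseline, white
#' detector noise, occasional single-channel spikes (cosmic rays / bad
#' pixels), and a peak response that grows with concentration but saturates
#' at the top of the range, `amplitude(c) = c / (1 + b c)`.
#'
#' @param axis_start,axis_stop,axis_step Wavenumber grid (cm^-1).
#' @param peaks Data frame with columns `center` (cm^-1), `width` (half width
#'   at half maximum, cm^-1) and `amplitude` (unit-concentration peak height,
#'   a.u.). At least one center must fall in each characteristic window
#'   (519-617 and 1292-1713 cm^-1).
#' @param response_sat Saturation constant `b` (ppm^-1) of the response
#'   `c / (1 + b c)`; `0` gives an exactly linear response.
#' @param baseline_amplitude Scale (a.u.) of the smooth fluorescence
#'   baseline (broad Gaussian bump plus a linear drift).
#' @param noise_sd Standard deviation (a.u.) of the additive Gaussian noise.
#' @param outlier_rate Probability per spectrum of one spiked channel.
#' @param n_samples Number of spectra (default 51, one per concentration).
#' @param conc_min,conc_max Concentration range in ppm; the grid is
#'   log-spaced so a 1-100 ppm gradient covers both decades evenly.
#'   `conc_min` must be positive (relative errors are undefined at 0 ppm).
#' @param seed Root seed; every random draw in the generator flows from it.
#' @return A `synth_config` list.
#' @examples
#' cfg <- synth_config(n_samples = 5, seed = 1)
#' concentration_grid(cfg)
#' @export
synth_config <- function(axis_start = 239, axis_stop = 2400, axis_step = 1,
                         peaks = ofloxacin_peaks(),
                         response_sat = 0.005,
                         baseline_amplitude = 10,
                         noise_sd = 0.1,
                         outlier_rate = 0.05,
                         n_samples = 51,
                         conc_min = 1, conc_max = 100,
                         seed = 1L) {
  cfg <- list(
    axis_start = axis_start, axis_stop = axis_stop, axis_step = axis_step,
    peaks = tibble::as_tibble(peaks), response_sat = response_sat,
    baseline_amplitude = baseline_amplitude, noise_sd = noise_sd,
    outlier_rate = outlier_rate, n_samples = as.integer(n_samples),
    conc_min = conc_min, conc_max = conc_max, seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

#' Default synthetic peak table
#'
#' Peak positions loosely follow strong ofloxacin SERS bands (ring breathing
#' and C-C/C-N stretching regions), with the dominant clusters inside the
#' two characteristic windows and a few weak bands elsewhere.
#'
#' @return A tibble with columns `center`, `width`, `amplitude`.
#' @export
ofloxacin_peaks <- function() {
  tibble::tribble(
    ~center, ~width, ~amplitude,
    540,      8,     0.45,
    578,     10,     1.00,
    604,      9,     0.30,
    762,     12,     0.15,
    1090,    14,     0.12,
    1340,    12,     0.55,
    1398,    11,     0.90,
    1538,    13,     0.75,
    1612,    10,     0.40,
    1720,    15,     0.10,
    2080,    20,     0.05
  )
}

validate_synth_config <- function(cfg) {
  p <- cfg$peaks
  if (!is.finite(cfg$axis_start) || !is.finite(cfg$axis_stop) ||
      cfg$axis_start >= cfg$axis_stop) {
    stop_config("axis_start must be < axis_stop")
  }
  if (!is.finite(cfg$axis_step) || cfg$axis_step <= 0) {
    stop_config("axis_step must be > 0")
  }
  if (!all(c("center", "width", "amplitude") %in% names(p)) || nrow(p) < 1) {
    stop_config("peaks need columns center, width, amplitude")
  }
  if (any(p$width <= 0) || any(p$amplitude < 0)) {
    stop_config("peak widths must be positive and amplitudes non-negative")
  }
  if (!any(p$center >= 519 & p$center <= 617)) {
    stop_config("at least one peak center must lie in [519, 617] cm^-1")
  }
  if (!any(p$center >= 1292 & p$center <= 1713)) {
    stop_config("at least one peak center must lie in [1292, 1713] cm^-1")
  }
  if (cfg$response_sat < 0) stop_config("response_sat must be >= 0")
  if (cfg$baseline_amplitude < 0) stop_config("baseline_amplitude must be >= 0")
  if (cfg$noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (cfg$outlier_rate < 0 || cfg$outlier_rate > 1) {
    stop_config("outlier_rate must be in [0, 1]")
  }
  if (cfg$n_samples < 1) stop_config("n_samples must be >= 1")
  if (!is.finite(cfg$conc_min) || cfg$conc_min <= 0) {
    stop_config("conc_min must be > 0 ppm (relative errors need nonzero truths)")
  }
  if (cfg$conc_max < cfg$conc_min) stop_config("conc_max must be >= conc_min")
  invisible(cfg)
}

#' Log-spaced concentration gradient
#'
#' Deterministic log-spaced grid of `n_samples` concentrations covering
#' `[conc_min, conc_max]` ppm, the simulated analogue of a serial-dilution
#' gradient spanning two decades.
#'
#' @param cfg A [synth_config()].
#' @return Numeric vector of ppm values (increasing).
#' @export
concentration_grid <- function(cfg) {
  validate_synth_config(cfg)
  if (cfg$n_samples == 1) return(cfg$conc_min)
  exp(seq(log(cfg$conc_min), log(cfg$conc_max), length.out = cfg$n_samples))
}

lorentzian <- function(x, center, width) {
  width^2 / ((x - center)^2 + width^2)
}

#' Generate a synthetic SERS dataset with ground truth
#'
#' Draws `n_samples` spectra on the configured grid. Each spectrum is
#' `signal + baseline + noise`, where the noiseless signal is a sum of
#' Lorentzian lines scaled by the saturating response `c / (1 + b c)`, the
#' baseline is a slowly varying positive curve (broad Gaussian bump plus
#' linear drift, with a small per-sample amplitude jitter), and the noise is
#' i.i.d. Gaussian. With probability `outlier_rate` one randomly chosen
#' channel per spectrum is replaced by a large positive spike. Everything is
#' reproducible from `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return A list with elements
#'   \describe{
#'     \item{spectra}{a [spectra_tbl][as_spectra] with ppm labels}
#'     \item{truth}{a list holding the axis, per-sample `concentration`,
#'       and the `signal`, `baseline` and `noise` matrices (samples x
#'       channels) plus an `outliers` tibble (`sample_id`, `wavenumber`,
#'       `value`); `signal + baseline + noise`, with the spiked channels
#'       overwritten by `value`, reconstructs the emitted intensities
#'       exactly.}
#'   }
#' @examples
#' out <- generate_spectra(synth_config(n_samples = 3, seed = 7))
#' dplyr::count(out$spectra, sample_id)
#' @export
generate_spectra <- function(cfg) {
  validate_synth_config(cfg)
  axis <- seq(cfg$axis_start, cfg$axis_stop, by = cfg$axis_step)
  n <- cfg$n_samples
  L <- length(axis)
  conc <- concentration_grid(cfg)

  # unit-concentration spectral profile (a.u. per unit response)
  profile <- rep(0, L)
  for (k in seq_len(nrow(cfg$peaks))) {
    profile <- profile + cfg$peaks$amplitude[k] *
      lorentzian(axis, cfg$peaks$center[k], cfg$peaks$width[k])
  }
  response <- conc / (1 + cfg$response_sat * conc)
  signal <- outer(response, profile)

  span <- cfg$axis_stop - cfg$axis_start
  bump <- exp(-((axis - (cfg$axis_start + 0.35 * span))^2) / (2 * (0.3 * span)^2))
  drift <- 0.4 * (1 - (axis - cfg$axis_start) / span)
  shape <- bump + drift

  with_seed(cfg$seed, {
    jitter <- stats::runif(n, 0.8, 1.2)
    baseline <- cfg$baseline_amplitude * outer(jitter, shape)
    noise <- matrix(stats::rnorm(n * L, sd = cfg$noise_sd), nrow = n)
    clean <- signal + baseline
    emitted <- clean + noise
    spiked <- stats::runif(n) < cfg$outlier_rate
    out_rows <- which(spiked)
    out_ch <- integer(0)
    out_val <- double(0)
    for (i in out_rows) {
      ch <- sample.int(L, 1L)
      val <- max(clean[i, ]) * stats::runif(1, 2, 5)
      emitted[i, ch] <- val
      out_ch <- c(out_ch, ch)
      out_val <- c(out_val, val)
    }
  })

  ids <- sprintf("S%02d", seq_len(n))
  spectra <- spectra_from_matrix(emitted, axis, sample_ids = ids,
                                 concentrations = conc)
  truth <- list(
    axis = axis,
    concentration = stats::setNames(conc, ids),
    signal = signal, baseline = baseline, noise = noise,
    outliers = tibble::tibble(
      sample_id = ids[out_rows],
      wavenumber = axis[out_ch],
      value = out_val
    )
  )
  list(spectra = spectra, truth = truth)
}
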