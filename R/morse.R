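#' Generalized Morse wavelet parameters
#'
#' The zeroth-order generalized Morse wavelet is defined in the frequency
#' domain as \eqn{\Psi(\omega) = a\,\omega^\beta e^{-\omega^\gamma}} for
#' \eqn{\omega > 0} and zero otherwise (an analytic wavelet: no response to
#' negative frequencies or DC). \eqn{\gamma = 3} gives a Gaussian-like
#' envelope; the product \eqn{\beta\gamma} is the time-bandwidth product,
#' trading frequency resolution against time resolution. The defaults
#' \eqn{\gamma = 3, \beta = 90} are the package's operating point for
#' breathing-band analysis of heart rate.
#'
#' @param gamma,beta positive shape parameters.
#' @return an object of class `morse_params` with fields `gamma`, `beta`,
#'   `time_bandwidth`.
#' @export
morse_params <- function(gamma = 3, beta = 90) {
  stopifnot(gamma > 0, beta > 0)
  structure(list(gamma = gamma, beta = beta, time_bandwidth = gamma * beta),
            class = "morse_params")
}

#' Modal (peak) frequency of the Morse wavelet
#'
#' Closed form \eqn{\omega_m = (\beta/\gamma)^{1/\gamma}} rad/s, where the
#' frequency-domain filter attains its maximum.
#'
#' @param params a [morse_params()].
#' @return modal frequency in rad/s.
#' @export
morse_modal_frequency <- function(params = morse_params()) {
  (params$beta / params$gamma)^(1 / params$gamma)
}

#' Evaluate the Morse filter on a radian-frequency grid
#'
#' Peak-normalized so that the filter equals 2 at its modal frequency
#' ("bandpass" normalization: a unit analytic exponential passes with unit
#' amplitude). Evaluated in log space, so large \eqn{\beta} does not
#' overflow.
#'
#' @param omega radian frequencies (values at `omega <= 0` return 0).
#' @param params a [morse_params()].
#' @return filter values, same length as `omega`.
#' @export
morse_filter <- function(omega, params = morse_params()) {
  g <- params$gamma; b <- params$beta
  wm <- (b / g)^(1 / g)
  out <- numeric(length(omega))
  pos <- which(omega > 0)
  if (length(pos)) {
    w <- omega[pos]
    lh <- log(2) + b * (log(w) - log(wm)) - (w^g - wm^g)
    out[pos] <- exp(lh)
  }
  out
}

# half-duration (seconds) after which edge effects are considered to have
# decayed for an analysis frequency f: 1.5 envelope e-folding times, with the
# Gaussian-like envelope SD sigma_t = sqrt(beta*gamma) / (2*pi*f)
morse_coi_seconds <- function(freq_hz, params) {
  1.5 * sqrt(2) * sqrt(params$beta * params$gamma) / (2 * pi * freq_hz)
}

#' Continuous Morse-wavelet transform on a fixed frequency grid
#'
#' FFT-domain multiplication per analysis frequency: each frequency bin gets
#' the analytic Morse filter rescaled so its modal frequency sits at the bin
#' frequency, which keeps the exact analytic filter shape on an arbitrary
#' (e.g. 0.02-Hz) grid. Coefficients are subsampled to the time-slice grid
#' (50 ms by default). The transform is linear in the input, and the input
#' mean is removed first.
#'
#' The record is zero-padded past both ends before filtering (to a fast FFT
#' length covering the longest wavelet), and slices closer to either record
#' edge than 1.5 envelope e-folding times of a bin's wavelet are flagged in
#' `coi_invalid` (cone of influence): inside that margin the wavelet sees
#' the padding, and such slices must not seed spectral tracks.
#'
#' @param x an [hr_series()] or numeric vector on a uniform grid.
#' @param freqs_hz strictly increasing analysis frequencies, all below the
#'   Nyquist frequency.
#' @param params a [morse_params()].
#' @param sample_rate_hz grid rate when `x` is a bare vector.
#' @param slice_ms time-slice step in milliseconds.
#' @return an object of class `tfa_map`: `coefficients` (complex,
#'   slices x frequencies), `power`, `freqs_hz`, `slice_times_s`,
#'   `slice_step_s`, `coi_invalid` (logical matrix), `filter_energy`
#'   (per-bin mean squared filter gain, used for PSD scaling), `params`,
#'   `input_fs`.
#' @export
cwt_morse <- function(x, freqs_hz, params = morse_params(),
                      sample_rate_hz = NULL, slice_ms = 50) {
  if (inherits(x, "hr_series")) {
    fs <- x$grid_rate_hz
    t0 <- x$times_s[1]
    x <- x$hr_bpm
  } else {
    fs <- sample_rate_hz
    t0 <- 0
    x <- as.numeric(x)
  }
  if (is.null(fs)) stop("sample_rate_hz required for a bare vector")
  freqs_hz <- as.numeric(freqs_hz)
  if (any(diff(freqs_hz) <= 0)) stop("freqs_hz must be strictly increasing")
  if (any(freqs_hz <= 0) || any(freqs_hz >= fs / 2))
    stop("analysis frequencies must lie in (0, Nyquist)")
  n <- length(x)
  x <- x - mean(x)

  # zero-pad past both ends so the lowest-frequency wavelet never wraps the
  # record onto itself; nextn keeps the FFT length highly composite
  pad <- ceiling(morse_coi_seconds(freqs_hz[1], params) * fs)
  m <- stats::nextn(n + 2L * pad)
  X <- stats::fft(c(x, numeric(m - n)))
  k <- 0:(m - 1)
  fk <- fs * k / m
  pos <- fk > 0 & fk <= fs / 2          # analytic: negative frequencies zeroed
  omega <- 2 * pi * fk
  wm <- morse_modal_frequency(params)

  step <- max(1L, round(slice_ms / 1000 * fs))
  idx <- seq(1L, n, by = step)
  nf <- length(freqs_hz)
  coef <- matrix(complex(real = 0), nrow = length(idx), ncol = nf)
  energy <- numeric(nf)
  for (j in seq_len(nf)) {
    H <- numeric(m)
    H[pos] <- morse_filter(omega[pos] * wm / (2 * pi * freqs_hz[j]), params)
    energy[j] <- mean(H^2)
    wj <- stats::fft(X * H, inverse = TRUE) / m
    coef[, j] <- wj[idx]
  }
  slice_times <- t0 + (idx - 1) / fs
  coi <- morse_coi_seconds(freqs_hz, params)
  t_end <- t0 + (n - 1) / fs
  coi_invalid <- outer(slice_times, seq_len(nf), function(tt, j)
    tt - t0 < coi[j] | t_end - tt < coi[j])

  structure(
    list(coefficients = coef, power = Mod(coef)^2, freqs_hz = freqs_hz,
         slice_times_s = slice_times, slice_step_s = step / fs,
         coi_invalid = coi_invalid, filter_energy = energy,
         params = params, input_fs = fs, n_input = n),
    class = "tfa_map")
}

#' @export
print.tfa_map <- function(x, ...) {
  cat(sprintf("<tfa_map> %d slices x %d freqs (%g-%g Hz), slice %g ms, gamma=%g beta=%g\n",
              nrow(x$coefficients), length(x$freqs_hz), min(x$freqs_hz),
              max(x$freqs_hz), 1000 * x$slice_step_s,
              x$params$gamma, x$params$beta))
  invisible(x)
}

#' Band-limited inverse wavelet reconstruction
#'
#' Rebuilds a real-valued narrow-band signal from the coefficients whose bin
#' frequency lies within `halfwidth_hz` of a (possibly time-varying) center
#' frequency; this is how the breathing signal is reconstructed around the
#' extracted breathing frequency. Normalized by the summed filter gains at
#' the center frequency so that a pure tone at a constant center is
#' recovered at its true amplitude.
#'
#' @param map a [cwt_morse()] map.
#' @param center_hz scalar or per-slice center frequency, Hz.
#' @param halfwidth_hz half-width of the reconstruction band, Hz.
#' @return numeric series on the slice grid.
#' @export
inverse_cwt_band <- function(map, center_hz, halfwidth_hz = 0.015) {
  ns <- nrow(map$coefficients)
  center <- rep_len(as.numeric(center_hz), ns)
  if (any(center < min(map$freqs_hz) - 1e-9 |
            center > max(map$freqs_hz) + 1e-9))
    stop("center_hz outside the analyzed frequency range")
  wm <- morse_modal_frequency(map$params)
  out <- numeric(ns)
  # centers are typically on the analysis grid: group identical values
  uc <- unique(center)
  for (cv in uc) {
    rows <- which(center == cv)
    bins <- which(abs(map$freqs_hz - cv) <= halfwidth_hz + 1e-12)
    if (!length(bins))
      stop(sprintf("empty reconstruction band at slice %d (center %.3f Hz)",
                   rows[1], cv))
    gains <- morse_filter(wm * cv / map$freqs_hz[bins], map$params) / 2
    out[rows] <- rowSums(Re(map$coefficients[rows, bins, drop = FALSE])) /
      sum(gains)
  }
  out
}

#' One-sided power spectral density estimate from a Morse map
#'
#' Rescales wavelet power by each bin's filter energy so that the expected
#' value for white noise equals the flat one-sided PSD (2 sigma^2 / fs);
#' this removes the constant-Q bandwidth growth of wavelet power with
#' frequency, making band integrals comparable across bands.
#'
#' @param map a [cwt_morse()] map.
#' @return matrix (slices x frequencies) of PSD estimates, units
#'   input-units squared per Hz.
#' @export
tfa_psd <- function(map) {
  sweep(map$power, 2, map$input_fs * map$filter_energy, "/") * 2
}
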