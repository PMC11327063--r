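#' Detect R peaks in a single-lead ECG
#'
#' Pan-Tompkins-style detector: 5-25 Hz zero-phase band-pass, derivative,
#' squaring, 150-ms moving-window integration, adaptive amplitude threshold
#' and a 250-ms refractory period (which caps the detectable rate at the
#' physiologic ceiling). Peak times are refined to the raw-signal maximum
#' near each integrated-energy peak.
#'
#' @param ecg an `ecg_signal` (list with `samples`, `sample_rate_hz`,
#'   optional `start_time_s`) or a numeric vector (then `sample_rate_hz`
#'   must be given).
#' @param sample_rate_hz sampling rate when `ecg` is a bare vector.
#' @param refractory_s minimum beat-to-beat distance, seconds.
#' @return strictly increasing R-peak times in seconds.
#' @export
detect_r_peaks <- function(ecg, sample_rate_hz = NULL, refractory_s = 0.25) {
  if (is.list(ecg)) {
    x <- ecg$samples
    fs <- ecg$sample_rate_hz
    t0 <- if (!is.null(ecg$start_time_s)) ecg$start_time_s else 0
  } else {
    x <- as.numeric(ecg)
    fs <- sample_rate_hz
    t0 <- 0
  }
  if (is.null(fs) || fs < 100)
    stop("R detection needs sample_rate_hz >= 100 Hz")
  x <- x - stats::median(x)
  if (length(x) < fs || stats::sd(x) < 1e-9)
    stop("no beats: empty or flat ECG signal")

  bf <- signal::butter(2, c(5, 25) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, x)
  d <- c(0, diff(bp)) * fs
  s <- d^2
  w <- max(3L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(s, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0

  n <- length(integ)
  loc <- which(integ[2:(n - 1)] > integ[1:(n - 2)] &
                 integ[2:(n - 1)] >= integ[3:n]) + 1L
  if (length(loc) == 0) stop("no beats: no energy peaks found")
  thr <- 0.2 * stats::quantile(integ[loc], 0.95, names = FALSE)
  loc <- loc[integ[loc] >= thr]
  if (length(loc) == 0) stop("no beats: all energy peaks below threshold")

  # refractory: accept strongest first, suppress neighbours within 250 ms
  ord <- loc[order(integ[loc], decreasing = TRUE)]
  accepted <- numeric(0)
  min_gap <- refractory_s * fs
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= min_gap))
      accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)

  # refine to the raw R apex within +/-80 ms
  half <- round(0.080 * fs)
  refine <- vapply(accepted, function(i) {
    lo <- max(1, i - half); hi <- min(length(x), i + half)
    lo + which.max(x[lo:hi]) - 1
  }, numeric(1))
  beats <- sort(unique(refine))
  if (length(beats) < 2) stop("no beats: fewer than two R peaks detected")
  t0 + (beats - 1) / fs
}

#' Instantaneous heart rate from R-peak times
#'
#' The instantaneous rate of each R-R interval, HR = 60 / (R-R interval), is
#' assigned at the interval midpoint and interpolated to a uniform grid with
#' a monotone piecewise-cubic scheme (no overshoot, hence no spurious
#' spectral content for the wavelet analysis). R-R intervals outside
#' 0.27-3 s are treated as artifacts and bridged by the interpolation rather
#' than deleted, preserving the uniform grid.
#'
#' @param beat_times_s strictly increasing R-peak times, seconds.
#' @param grid_rate_hz output grid rate; the default 20 Hz gives one sample
#'   per 50-ms time-frequency slice.
#' @param duration_s optional record length; defaults to the last beat time.
#' @param rr_valid_s artifact gate on the R-R interval, seconds.
#' @return an [hr_series()].
#' @export
hr_from_beats <- function(beat_times_s, grid_rate_hz = 20, duration_s = NULL,
                          rr_valid_s = c(0.27, 3)) {
  b <- as.numeric(beat_times_s)
  if (length(b) < 3) stop("need at least 3 beats")
  if (any(diff(b) <= 0)) stop("beat times must be strictly increasing")
  rr <- diff(b)
  mid <- (b[-1] + b[-length(b)]) / 2
  ok <- rr >= rr_valid_s[1] & rr <= rr_valid_s[2]
  if (!any(ok)) stop("no physiologic R-R intervals")
  hr_inst <- 60 / rr[ok]
  mid <- mid[ok]

  dur <- if (is.null(duration_s)) max(b) else duration_s
  t <- seq(0, dur - 1e-9, by = 1 / grid_rate_hz)
  if (length(mid) == 1) {
    hr <- rep(hr_inst, length(t))
  } else {
    f <- stats::splinefun(mid, hr_inst, method = "monoH.FC")
    hr <- f(pmin(pmax(t, mid[1]), mid[length(mid)]))  # clamp: no cubic extrapolation
  }
  hr_series(hr, t, grid_rate_hz, beat_times_s = b)
}

# local maxima with topographic prominence >= thr and a minimum spacing
find_crests <- function(x, min_dist = 1L, prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  loc <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(loc)) return(integer(0))
  prom <- vapply(loc, function(p) {
    i <- p
    lmin <- x[p]
    while (i > 1 && x[i - 1] <= x[p]) { i <- i - 1; lmin <- min(lmin, x[i]) }
    lbase <- if (i == 1 && x[i] <= x[p]) min(lmin, x[1]) else lmin
    i <- p
    rmin <- x[p]
    while (i < n && x[i + 1] <= x[p]) { i <- i + 1; rmin <- min(rmin, x[i]) }
    rbase <- rmin
    x[p] - max(lbase, rbase)
  }, numeric(1))
  loc <- loc[prom >= prominence]
  if (!length(loc)) return(integer(0))
  ord <- loc[order(x[loc], decreasing = TRUE)]
  keep <- numeric(0)
  for (i in ord)
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  sort(keep)
}

#' Gold-standard breathing rate from a pressure-flow signal
#'
#' Flow crests (one per breathing cycle) are located with prominence-based
#' peak picking; the prominence floor is a fraction of the signal's
#' interquartile range, which makes the detection robust to baseline drift.
#' Crests must additionally rise the same fraction of the IQR above the
#' median level, which rejects noise bumps inside flat apnea stretches.
#' The instantaneous rate BR = 60 / (crest-crest interval) is assigned at
#' interval midpoints and interpolated to the common uniform grid.
#'
#' @param flow a `flow_signal` (list with `samples`, `sample_rate_hz`) or a
#'   numeric vector plus `sample_rate_hz`.
#' @param sample_rate_hz flow sampling rate when `flow` is a bare vector.
#' @param grid_rate_hz output grid rate (shared with the heart-rate grid).
#' @param prominence_frac prominence floor as a fraction of IQR.
#' @param min_period_s minimum crest spacing, seconds (27 bpm breathing has
#'   a 2.2-s period; the default leaves headroom).
#' @param duration_s optional record length for the output grid.
#' @return a [br_series()] with `source = "pressure"`; crest times are kept
#'   in attribute `crest_times_s`.
#' @export
br_from_flow <- function(flow, sample_rate_hz = NULL, grid_rate_hz = 20,
                         prominence_frac = 0.25, min_period_s = 1.8,
                         duration_s = NULL) {
  if (is.list(flow)) {
    x <- flow$samples
    fs <- flow$sample_rate_hz
  } else {
    x <- as.numeric(flow)
    fs <- sample_rate_hz
  }
  if (is.null(fs) || fs <= 0) stop("sample_rate_hz required")
  if (any(!is.finite(x))) stop("flow samples must be finite")
  # a flat (apnea) stretch between deep troughs gives even a noise bump a
  # large topographic prominence, so a height floor is applied as well
  prom <- prominence_frac * stats::IQR(x)
  idx <- find_crests(x, min_dist = round(min_period_s * fs), prominence = prom)
  idx <- idx[x[idx] >= stats::median(x) + prom]
  if (length(idx) < 2) stop("fewer than 2 flow crests detected")
  crest_t <- (idx - 1) / fs
  cc <- diff(crest_t)
  mid <- (crest_t[-1] + crest_t[-length(crest_t)]) / 2
  br_inst <- 60 / cc

  dur <- if (is.null(duration_s)) length(x) / fs else duration_s
  t <- seq(0, dur - 1e-9, by = 1 / grid_rate_hz)
  if (length(mid) == 1) {
    br <- rep(br_inst, length(t))
  } else {
    f <- stats::splinefun(mid, br_inst, method = "monoH.FC")
    br <- f(pmin(pmax(t, mid[1]), mid[length(mid)]))
  }
  out <- br_series(br, t, grid_rate_hz, source = "pressure")
  attr(out, "crest_times_s") <- crest_t
  out
}
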