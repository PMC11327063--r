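#' Define a synthetic cardiorespiratory scenario
#'
#' Builds the parameter set for the synthetic generator. The generator
#' produces an RSA-modulated heart rate together with its ground truth
#' (instantaneous breathing rate, breath crest times and the pure RSA
#' component), a matched pressure-flow signal with one crest per breath, and
#' optionally a stereotyped single-lead ECG. The signal model is
#'
#' \deqn{HR(t) = HR_0 + A_{RSA} \sin\phi(t) + \sum_k I_k(t) + A_{LF}
#'   \sin(2\pi f_{LF} t + \theta) + \epsilon(t)}
#'
#' with breathing phase \eqn{\phi(t) = 2\pi \int_0^t f_{BR}(u)\,du}. The RSA
#' term is the persistent, smoothly drifting spectral component in the
#' 0.15-0.45 Hz band that the spectral-continuity extractor tracks;
#' interferers \eqn{I_k} are transient sinusoids of comparable or greater
#' power that emulate movement and autonomic artifacts; inside apnea windows
#' the RSA term (and the flow signal) vanishes.
#'
#' @param duration_s record length, seconds.
#' @param hr_baseline mean heart rate, bpm.
#' @param rsa_amplitude RSA modulation depth, bpm. The depth is not pinned
#'   down by sleep physiology to a single value; 2 bpm (mid of the plausible
#'   1-3 bpm range) is the package default.
#' @param br_trajectory breathing-rate trajectory in breaths per minute:
#'   a single number (constant), a two-column data frame of
#'   `(time_s, br_bpm)` knots (piecewise-linear, held outside the knots), or
#'   a function of time. Must stay within 9-27 bpm (0.15-0.45 Hz).
#' @param interferers data frame with columns `start_s`, `stop_s`,
#'   `freq_hz`, `amplitude_bpm`; transient additive sinusoids. `NULL` for
#'   none.
#' @param apnea_windows two-column matrix/data frame of disjoint
#'   `(start_s, stop_s)` windows where breathing stops. `NULL` for none.
#' @param lf_noise_amp amplitude (bpm) of a slow sympathetic-like drift.
#' @param lf_drift_hz frequency of that drift, Hz (low-frequency band).
#' @param noise_sd_bpm SD of additive white measurement noise, bpm.
#' @param sample_rate_hz grid rate of the simulated heart rate, Hz.
#' @param seed integer seed; identical scenarios are bit-reproducible.
#' @return an object of class `sim_scenario`.
#' @seealso [simulate_heart_rate()], [simulate_flow()], [simulate_ecg()]
#' @export
sim_scenario <- function(duration_s = 600,
                         hr_baseline = 70,
                         rsa_amplitude = 2,
                         br_trajectory = 15,
                         interferers = NULL,
                         apnea_windows = NULL,
                         lf_noise_amp = 1,
                         lf_drift_hz = 0.03,
                         noise_sd_bpm = 0,
                         sample_rate_hz = 20,
                         seed = 1L) {
  stopifnot(duration_s > 0, hr_baseline > 0, rsa_amplitude >= 0,
            lf_noise_amp >= 0, noise_sd_bpm >= 0)
  if (sample_rate_hz < 2)
    stop("sample_rate_hz must be at least 2 Hz")
  br_fun <- as_br_trajectory(br_trajectory)
  tt <- seq(0, duration_s, by = 1)
  brv <- br_fun(tt)
  if (any(!is.finite(brv)) || any(brv < 9) || any(brv > 27))
    stop("br_trajectory leaves the representable 9-27 bpm band ",
         "(0.15-0.45 Hz); the extractor cannot encode such ground truth")
  if (!is.null(interferers)) {
    interferers <- as.data.frame(interferers)
    stopifnot(all(c("start_s", "stop_s", "freq_hz", "amplitude_bpm") %in%
                    names(interferers)))
    stopifnot(all(interferers$stop_s > interferers$start_s))
  }
  if (!is.null(apnea_windows)) {
    apnea_windows <- as.matrix(as.data.frame(apnea_windows))[, 1:2, drop = FALSE]
    colnames(apnea_windows) <- c("start_s", "stop_s")
    if (nrow(apnea_windows) > 1) {
      o <- order(apnea_windows[, 1])
      apnea_windows <- apnea_windows[o, , drop = FALSE]
      if (any(apnea_windows[-1, 1] < apnea_windows[-nrow(apnea_windows), 2]))
        stop("apnea windows must be disjoint")
    }
  }
  structure(
    list(duration_s = duration_s, hr_baseline = hr_baseline,
         rsa_amplitude = rsa_amplitude, br_trajectory = br_fun,
         interferers = interferers, apnea_windows = apnea_windows,
         lf_noise_amp = lf_noise_amp, lf_drift_hz = lf_drift_hz,
         noise_sd_bpm = noise_sd_bpm, sample_rate_hz = sample_rate_hz,
         seed = as.integer(seed)),
    class = "sim_scenario")
}

# normalise the user-facing trajectory spec to a vectorised function of time
as_br_trajectory <- function(x) {
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1) {
    force(x)
    return(function(t) rep_len(x, length(t)))
  }
  if (is.data.frame(x) || is.matrix(x)) {
    x <- as.data.frame(x)
    f <- stats::approxfun(x[[1]], x[[2]], rule = 2)
    return(f)
  }
  stop("br_trajectory must be a constant, a (time_s, br_bpm) table or a function")
}

with_sim_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

in_windows <- function(t, windows) {
  if (is.null(windows) || nrow(windows) == 0) return(rep(FALSE, length(t)))
  inside <- rep(FALSE, length(t))
  for (i in seq_len(nrow(windows)))
    inside <- inside | (t >= windows[i, 1] & t < windows[i, 2])
  inside
}

cumtrapz_dt <- function(y, dt) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2)) * dt
}

#' Simulate an RSA-modulated heart rate with known ground truth
#'
#' @param scenario a [sim_scenario()].
#' @return a list with elements
#'   `hr` (an [hr_series()] on the scenario grid; `beat_times_s` empty
#'   because no beats were involved) and
#'   `truth` (list: `times_s`, `br_true` instantaneous breathing rate in bpm
#'   with `NA` inside apnea windows, `breath_crest_times` in seconds
#'   excluding apnea, `rsa_component` the pure RSA modulation in bpm,
#'   `hr_bpm` a copy of the full heart rate, `phase` the breathing phase in
#'   radians).
#' @export
simulate_heart_rate <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  fs <- scenario$sample_rate_hz
  n <- round(scenario$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  br <- scenario$br_trajectory(t)
  if (any(!is.finite(br)) || any(br < 9) || any(br > 27))
    stop("br_trajectory leaves the representable 9-27 bpm band")
  phase <- 2 * pi * cumtrapz_dt(br / 60, 1 / fs)
  apnea <- in_windows(t, scenario$apnea_windows)
  rsa <- scenario$rsa_amplitude * sin(phase)
  rsa[apnea] <- 0

  hr <- scenario$hr_baseline + rsa
  if (!is.null(scenario$interferers)) {
    for (i in seq_len(nrow(scenario$interferers))) {
      w <- scenario$interferers[i, ]
      act <- t >= w$start_s & t < w$stop_s
      # half-cosine on/off ramps bound spectral splatter at the window edges
      ramp <- min(1, (w$stop_s - w$start_s) / 4)
      g <- numeric(n)
      tr <- t[act] - w$start_s
      td <- w$stop_s - w$start_s
      env <- pmin(1, pmin(tr, td - tr) / ramp)
      env <- sin(pmin(env, 1) * pi / 2)
      g[act] <- env
      hr <- hr + w$amplitude_bpm * g * sin(2 * pi * w$freq_hz * (t - w$start_s))
    }
  }
  noise <- with_sim_seed(scenario$seed, {
    th <- stats::runif(1, 0, 2 * pi)
    lf <- scenario$lf_noise_amp * sin(2 * pi * scenario$lf_drift_hz * t + th)
    wn <- if (scenario$noise_sd_bpm > 0)
      stats::rnorm(n, 0, scenario$noise_sd_bpm) else numeric(n)
    lf + wn
  })
  hr <- hr + noise

  # breath crests: flow = sin(phase) peaks where phase = pi/2 + 2*pi*k
  crest_phases <- seq(pi / 2, max(phase), by = 2 * pi)
  crest_times <- stats::approx(phase, t, xout = crest_phases,
                               ties = "ordered")$y
  crest_times <- crest_times[!is.na(crest_times)]
  crest_times <- crest_times[!in_windows(crest_times, scenario$apnea_windows)]

  br_true <- br
  br_true[apnea] <- NA_real_

  truth <- list(times_s = t, br_true = br_true,
                breath_crest_times = crest_times,
                rsa_component = rsa, hr_bpm = hr, phase = phase,
                apnea = apnea)
  list(hr = hr_series(hr, t, fs), truth = truth)
}

#' Simulate the matched pressure-flow signal
#'
#' One crest per entry of `truth$breath_crest_times`; the trace is flat
#' (apart from tiny sensor noise) inside apnea windows.
#'
#' @param truth ground truth from [simulate_heart_rate()].
#' @param scenario the same [sim_scenario()].
#' @return a `flow_signal` list: `samples`, `sample_rate_hz`, `start_time_s`.
#' @export
simulate_flow <- function(truth, scenario) {
  fs <- scenario$sample_rate_hz
  t <- truth$times_s
  x <- sin(truth$phase)
  x[truth$apnea] <- 0
  x <- x + with_sim_seed(scenario$seed + 1L, stats::rnorm(length(t), 0, 0.005))
  structure(list(samples = x, sample_rate_hz = fs, start_time_s = 0),
            class = "flow_signal")
}

#' Simulate a stereotyped single-lead ECG
#'
#' Beat times come from integrate-and-fire on the simulated heart rate: a
#' beat fires whenever \eqn{\int HR(t)/60\,dt} crosses an integer, so the
#' instantaneous R-R interval encodes the RSA modulation exactly. Each beat
#' places an 80-ms raised-cosine QRS spike; realistic P/T morphology is out
#' of scope (any threshold/derivative R detector only needs the spike).
#'
#' @param truth ground truth from [simulate_heart_rate()].
#' @param scenario the same [sim_scenario()].
#' @param ecg_rate_hz ECG sampling rate, Hz (>= 100).
#' @return an `ecg_signal` list: `samples` (mV), `sample_rate_hz`,
#'   `start_time_s`, `beat_times_s` (the ground-truth template times).
#' @export
simulate_ecg <- function(truth, scenario, ecg_rate_hz = 200) {
  stopifnot(ecg_rate_hz >= 100)
  fs_hr <- scenario$sample_rate_hz
  cumbeats <- cumtrapz_dt(truth$hr_bpm / 60, 1 / fs_hr)
  ks <- seq_len(floor(max(cumbeats)))
  beat_times <- stats::approx(cumbeats, truth$times_s, xout = ks,
                              ties = "ordered")$y
  beat_times <- beat_times[!is.na(beat_times)]

  n <- round(scenario$duration_s * ecg_rate_hz)
  x <- with_sim_seed(scenario$seed + 2L, stats::rnorm(n, 0, 0.005))
  half <- round(0.040 * ecg_rate_hz)                # 80 ms raised cosine
  tpl <- 0.5 * (1 + cos(pi * seq(-half, half) / half))
  for (bt in beat_times) {
    i0 <- round(bt * ecg_rate_hz) + 1
    lo <- i0 - half; hi <- i0 + half
    sel <- lo:hi >= 1 & lo:hi <= n
    idx <- (lo:hi)[sel]
    x[idx] <- x[idx] + tpl[sel]
  }
  structure(list(samples = x, sample_rate_hz = ecg_rate_hz,
                 start_time_s = 0, beat_times_s = beat_times),
            class = "ecg_signal")
}
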