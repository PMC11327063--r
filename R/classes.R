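#' Uniformly sampled instantaneous heart-rate series
#'
#' Container for instantaneous heart rate (bpm) on a strictly uniform time
#' grid, as produced by [hr_from_beats()]. The original R-peak times are kept
#' so the beat-to-beat (R-R) information is never lost by the gridding.
#'
#' @param hr_bpm numeric vector of heart rate values in beats per minute.
#' @param times_s uniform time grid in seconds (same length as `hr_bpm`).
#' @param grid_rate_hz sampling rate of the grid in Hz.
#' @param beat_times_s optional vector of the R-peak times (seconds) the
#'   series was derived from.
#' @return an object of class `hr_series`.
#' @export
hr_series <- function(hr_bpm, times_s, grid_rate_hz, beat_times_s = numeric()) {
  stopifnot(length(hr_bpm) == length(times_s), grid_rate_hz > 0)
  if (length(times_s) > 2) {
    dt <- diff(times_s)
    if (max(abs(dt - 1 / grid_rate_hz)) > 1e-6 / grid_rate_hz)
      stop("times_s is not a uniform grid at grid_rate_hz")
  }
  if (any(!is.na(hr_bpm) & hr_bpm <= 0))
    stop("hr_bpm must be positive")
  structure(
    list(hr_bpm = as.numeric(hr_bpm), times_s = as.numeric(times_s),
         grid_rate_hz = grid_rate_hz,
         beat_times_s = as.numeric(beat_times_s)),
    class = "hr_series")
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("<hr_series> %d samples @ %g Hz, %.1f-%.1f s, mean %.1f bpm, %d beats\n",
              length(x$hr_bpm), x$grid_rate_hz, min(x$times_s), max(x$times_s),
              mean(x$hr_bpm, na.rm = TRUE), length(x$beat_times_s)))
  invisible(x)
}

#' Breathing-rate series with provenance
#'
#' Breathing rate in breaths per minute on a uniform grid. `source` records
#' how the series was obtained: `"pressure"` (flow-meter gold standard),
#' `"scedr"` (spectral-continuity extraction) or `"maxpower"` (max-power
#' baseline). `confidence` flags each sample as `"tracked"` (a spectral peak
#' or flow crest interval directly supported it) or `"gap-bridged"`
#' (held/interpolated across a dropout such as apnea).
#'
#' @param br_bpm numeric breathing rate, breaths per minute.
#' @param times_s uniform time grid, seconds.
#' @param grid_rate_hz grid rate, Hz.
#' @param source one of `"pressure"`, `"scedr"`, `"maxpower"`.
#' @param confidence character vector, `"tracked"` or `"gap-bridged"`,
#'   recycled if length 1.
#' @return an object of class `br_series`.
#' @export
br_series <- function(br_bpm, times_s, grid_rate_hz,
                      source = c("pressure", "scedr", "maxpower"),
                      confidence = "tracked") {
  source <- match.arg(source)
  stopifnot(length(br_bpm) == length(times_s))
  confidence <- rep_len(confidence, length(br_bpm))
  if (!all(confidence %in% c("tracked", "gap-bridged")))
    stop("confidence must be 'tracked' or 'gap-bridged'")
  if (source %in% c("scedr", "maxpower")) {
    ok <- is.na(br_bpm) | (br_bpm >= 9 - 1e-9 & br_bpm <= 27 + 1e-9)
    if (!all(ok))
      stop("spectral-EDR breathing rate outside the 9-27 bpm search band")
  }
  structure(
    list(br_bpm = as.numeric(br_bpm), times_s = as.numeric(times_s),
         grid_rate_hz = grid_rate_hz, source = source,
         confidence = confidence),
    class = "br_series")
}

#' @export
print.br_series <- function(x, ...) {
  cat(sprintf("<br_series:%s> %d samples @ %g Hz, median %.1f bpm, %.1f%% gap-bridged\n",
              x$source, length(x$br_bpm), x$grid_rate_hz,
              stats::median(x$br_bpm, na.rm = TRUE),
              100 * mean(x$confidence == "gap-bridged")))
  invisible(x)
}

#' Thirty-second epoch hypnogram
#'
#' @param labels character vector of sleep-stage labels, one per epoch, from
#'   `ECW`/`W`, `N1`, `N2`, `N3`, `REM`, `REM0`.
#' @param epoch_s epoch length in seconds (30 by convention).
#' @param start_s start time of the first epoch.
#' @return a `hypnogram` data frame with columns `epoch_index`,
#'   `epoch_start_s`, `label`.
#' @export
hypnogram <- function(labels, epoch_s = 30, start_s = 0) {
  labels <- as.character(labels)
  valid <- c("ECW", "W", "N1", "N2", "N3", "REM", "REM0")
  if (!all(labels %in% valid))
    stop("invalid stage label(s): ",
         paste(unique(setdiff(labels, valid)), collapse = ", "))
  out <- data.frame(
    epoch_index = seq_along(labels),
    epoch_start_s = start_s + (seq_along(labels) - 1) * epoch_s,
    label = labels,
    stringsAsFactors = FALSE)
  attr(out, "epoch_s") <- epoch_s
  class(out) <- c("hypnogram", "data.frame")
  out
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %g s\n", nrow(x), attr(x, "epoch_s")))
  print(table(x$label))
  invisible(x)
}

# epoch membership of grid times: epoch k covers [start, start + epoch_s)
epoch_of_times <- function(times_s, hypno) {
  epoch_s <- attr(hypno, "epoch_s")
  k <- floor((times_s - hypno$epoch_start_s[1]) / epoch_s) + 1L
  k[k < 1L | k > nrow(hypno)] <- NA_integer_
  k
}
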