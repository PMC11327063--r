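#' Configuration for the spectral-continuity pipeline
#'
#' All tunable constants of the extraction in one place. Defaults:
#' analysis grid 0.05-0.45 Hz in 0.02-Hz steps with 50-ms slices; breathing
#' search band 0.15-0.45 Hz; the significance threshold is 20 % of the
#' slice's maximum power taken over the wider 0.05-0.45 Hz spectrum, which
#' suppresses breathing-band peaks that are small compared to slower
#' autonomic components; peaks link into tracks when consecutive
#' frequencies differ by at most one bin (0.02 Hz), tracks tolerate
#' dropouts up to 40 slices (2 s), and a broken breathing track may rejoin
#' a candidate starting within 1200 slices (60 s, spanning typical apneas);
#' equal-duration tracks are tie-broken by higher mean power; the breathing
#' signal is reconstructed in a +/-0.015 Hz window around the extracted
#' frequency.
#'
#' @param ... overrides for any of the defaults listed in the source.
#' @return a named list of class `scedr_config`.
#' @export
scedr_config <- function(...) {
  cfg <- list(
    gamma = 3, beta = 90,
    freq_min = 0.05, freq_max = 0.45, freq_step = 0.02,
    slice_ms = 50,
    search_band = c(0.15, 0.45),
    threshold_band = c(0.05, 0.45),
    threshold_frac = 0.20,
    link_tolerance_hz = 0.02,
    gap_tolerance_slices = 40L,
    rejoin_window_slices = 1200L,
    reconstruct_halfwidth_hz = 0.015,
    grid_rate_hz = 20)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$threshold_band[1] <= cfg$search_band[1],
            cfg$threshold_band[2] >= cfg$search_band[2],
            cfg$threshold_frac > 0, cfg$threshold_frac < 1)
  structure(cfg, class = "scedr_config")
}

#' Analysis frequency grid implied by a configuration
#' @param config a [scedr_config()].
#' @return numeric vector of analysis frequencies, Hz.
#' @export
tfa_frequency_grid <- function(config = scedr_config()) {
  seq(config$freq_min, config$freq_max, by = config$freq_step)
}

#' Morse map of a heart-rate series under a configuration
#'
#' Convenience wrapper: [cwt_morse()] on the configured grid and wavelet.
#' @param hr an [hr_series()].
#' @param config a [scedr_config()].
#' @return a `tfa_map`.
#' @export
tfa_heart_rate <- function(hr, config = scedr_config()) {
  cwt_morse(hr, tfa_frequency_grid(config),
            morse_params(config$gamma, config$beta),
            slice_ms = config$slice_ms)
}

#' Extract significant spectral peaks per time slice
#'
#' Local maxima of the per-slice power distribution within the search band.
#' A peak is significant when its power reaches `threshold_frac` of the
#' slice's maximum power over the (wider) threshold band; insignificant
#' peaks are dropped, as are peaks inside the cone of influence. Slices
#' within the search band's worst-case cone of influence of either record
#' edge yield no peaks at all (edge buffer): there the breathing-band bins
#' are already masked and the relative threshold would otherwise be set by
#' truncation residue in the remaining high-frequency bins.
#'
#' @param map a [cwt_morse()] map.
#' @param search_band numeric length 2, Hz; peaks are sought here.
#' @param threshold_band numeric length 2, Hz; the slice maximum defining
#'   the dynamic threshold is taken here (must contain `search_band`).
#' @param threshold_frac significance fraction of the slice maximum.
#' @param edge_buffer_s length of the edge buffer in seconds; `NULL` (the
#'   default) uses the cone of influence of the search band's lowest
#'   frequency. Set to 0 for slice-local analysis of interior data.
#' @return data frame with columns `slice`, `freq_hz`, `power`.
#' @export
extract_slice_peaks <- function(map, search_band = c(0.15, 0.45),
                                threshold_band = c(0.05, 0.45),
                                threshold_frac = 0.20,
                                edge_buffer_s = NULL) {
  if (threshold_band[1] > search_band[1] + 1e-12 ||
        threshold_band[2] < search_band[2] - 1e-12)
    stop("threshold_band must contain search_band")
  P <- map$power
  f <- map$freqs_hz
  valid <- !map$coi_invalid
  tb <- f >= threshold_band[1] - 1e-9 & f <= threshold_band[2] + 1e-9
  sb <- f >= search_band[1] - 1e-9 & f <= search_band[2] + 1e-9
  if (is.null(edge_buffer_s))
    edge_buffer_s <- morse_coi_seconds(search_band[1], map$params)
  if (edge_buffer_s > 0) {
    tt <- map$slice_times_s
    edge <- tt - tt[1] < edge_buffer_s | tt[length(tt)] - tt < edge_buffer_s
    valid[edge, ] <- FALSE
  }

  Pt <- P
  Pt[!valid] <- NA_real_
  Pt[, !tb] <- NA_real_
  slice_max <- apply(Pt, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  thr <- threshold_frac * slice_max

  nf <- length(f)
  is_max <- matrix(FALSE, nrow(P), nf)
  for (j in which(sb)) {
    left <- if (j > 1) P[, j] > P[, j - 1] else TRUE
    right <- if (j < nf) P[, j] >= P[, j + 1] else TRUE
    is_max[, j] <- left & right
  }
  sig <- is_max & valid & !is.na(thr) & P >= thr & P > 0
  idx <- which(sig, arr.ind = TRUE)
  out <- data.frame(slice = idx[, 1], freq_hz = f[idx[, 2]],
                    power = P[idx])
  out[order(out$slice, out$freq_hz), , drop = FALSE]
}

#' Link per-slice peaks into frequency tracks
#'
#' Greedy forward linking: walking the slices in time order, each open track
#' tries to extend to the peak of the current slice closest to its last
#' frequency, provided the jump does not exceed `link_tolerance_hz`; each
#' peak joins at most one track (conflicts resolved by smallest jump, ties
#' by older track then lower frequency). A track survives dropouts of up to
#' `gap_tolerance_slices` missing slices; peaks claimed by no track start
#' new tracks. Runs in linear time in the number of peaks.
#'
#' @param peaks data frame from [extract_slice_peaks()].
#' @param link_tolerance_hz maximum frequency jump between consecutive
#'   peaks of a track, Hz.
#' @param gap_tolerance_slices maximum number of missing slices inside a
#'   track.
#' @return list of `freq_track` objects, each with `slices`, `freqs`,
#'   `powers`, `start_slice`, `end_slice`, `duration_slices`, `mean_power`.
#' @export
build_tracks <- function(peaks, link_tolerance_hz = 0.02,
                         gap_tolerance_slices = 40L) {
  n <- nrow(peaks)
  if (is.null(n) || n == 0) return(list())
  eps <- 1e-9
  track_of <- integer(n)
  open_id <- integer(0); open_slice <- integer(0); open_freq <- numeric(0)
  next_id <- 1L
  rows_by_slice <- split(seq_len(n), peaks$slice)
  slices <- as.integer(names(rows_by_slice))

  for (si in seq_along(slices)) {
    s <- slices[si]
    keep <- open_slice >= s - gap_tolerance_slices - 1L
    open_id <- open_id[keep]; open_slice <- open_slice[keep]
    open_freq <- open_freq[keep]
    rows <- rows_by_slice[[si]]
    fpk <- peaks$freq_hz[rows]
    taken_peak <- rep(FALSE, length(rows))
    if (length(open_id)) {
      d <- abs(outer(open_freq, fpk, "-"))
      d[d > link_tolerance_hz + eps] <- NA_real_
      taken_track <- rep(FALSE, length(open_id))
      while (any(is.finite(d))) {
        m <- min(d, na.rm = TRUE)
        hit <- which(abs(d - m) <= eps, arr.ind = TRUE)
        # deterministic tie-break: oldest track (lowest id), then lowest freq
        hit <- hit[order(open_id[hit[, 1]], fpk[hit[, 2]]), , drop = FALSE]
        ti <- hit[1, 1]; pj <- hit[1, 2]
        track_of[rows[pj]] <- open_id[ti]
        open_slice[ti] <- s
        open_freq[ti] <- fpk[pj]
        taken_track[ti] <- TRUE
        taken_peak[pj] <- TRUE
        d[ti, ] <- NA_real_
        d[, pj] <- NA_real_
      }
    }
    new_rows <- rows[!taken_peak]
    if (length(new_rows)) {
      ids <- seq.int(next_id, length.out = length(new_rows))
      track_of[new_rows] <- ids
      open_id <- c(open_id, ids)
      open_slice <- c(open_slice, rep(s, length(new_rows)))
      open_freq <- c(open_freq, peaks$freq_hz[new_rows])
      next_id <- next_id + length(new_rows)
    }
  }

  lapply(split(seq_len(n), track_of), function(rows) {
    rows <- rows[order(peaks$slice[rows])]
    sl <- peaks$slice[rows]
    structure(
      list(slices = sl, freqs = peaks$freq_hz[rows],
           powers = peaks$power[rows],
           start_slice = sl[1], end_slice = sl[length(sl)],
           duration_slices = sl[length(sl)] - sl[1] + 1L,
           mean_power = mean(peaks$power[rows])),
      class = "freq_track")
  })
}

#' @export
print.freq_track <- function(x, ...) {
  cat(sprintf("<freq_track> slices %d-%d (duration %d), %.3f-%.3f Hz, mean power %.3g\n",
              x$start_slice, x$end_slice, x$duration_slices,
              min(x$freqs), max(x$freqs), x$mean_power))
  invisible(x)
}

#' Select the breathing track and fill a per-slice frequency
#'
#' The longest track (most slices from first to last peak) wins; equal
#' durations are tie-broken by higher mean power. Slices not covered by the
#' winner are bridged: after (and before) the winner, the candidate track
#' whose starting frequency is closest to the last valid frequency is
#' appended if it starts within `rejoin_window_slices`; remaining gaps hold
#' the last valid frequency. Samples at actual track peaks are flagged
#' `tracked`; everything interpolated or held is `gap-bridged`.
#'
#' @param tracks list from [build_tracks()].
#' @param n_slices total number of slices to fill.
#' @param previous_track optional `freq_track` from an earlier record
#'   segment; used as fallback when no tracks exist at all.
#' @param rejoin_window_slices how far ahead a candidate may start and
#'   still be joined to the breathing track.
#' @return list: `freq_hz` (length `n_slices`), `confidence`
#'   (`tracked`/`gap-bridged`), `selected` (indices into `tracks` in time
#'   order), `winner` (index of the longest track).
#' @export
select_breathing_track <- function(tracks, n_slices,
                                   previous_track = NULL,
                                   rejoin_window_slices = 1200L) {
  if (!length(tracks)) {
    if (is.null(previous_track))
      stop("no respiratory component: no spectral tracks found")
    f <- previous_track$freqs[length(previous_track$freqs)]
    return(list(freq_hz = rep(f, n_slices),
                confidence = rep("gap-bridged", n_slices),
                selected = integer(0), winner = NA_integer_))
  }
  dur <- vapply(tracks, `[[`, integer(1), "duration_slices")
  pow <- vapply(tracks, `[[`, numeric(1), "mean_power")
  start <- vapply(tracks, `[[`, integer(1), "start_slice")
  end <- vapply(tracks, `[[`, integer(1), "end_slice")
  ord <- order(-dur, -pow, start)
  winner <- ord[1]

  selected <- winner
  # forward rejoining across dropouts (e.g. apnea)
  repeat {
    last <- selected[length(selected)]
    cand <- which(start > end[last] &
                    start - end[last] <= rejoin_window_slices)
    cand <- setdiff(cand, selected)
    if (!length(cand)) break
    f_last <- tracks[[last]]$freqs[length(tracks[[last]]$freqs)]
    f_start <- vapply(cand, function(i) tracks[[i]]$freqs[1], numeric(1))
    co <- order(abs(f_start - f_last), -dur[cand], start[cand])
    selected <- c(selected, cand[co[1]])
  }
  # backward rejoining before the winner
  repeat {
    first <- selected[1]
    cand <- which(end < start[first] &
                    start[first] - end <= rejoin_window_slices)
    cand <- setdiff(cand, selected)
    if (!length(cand)) break
    f_first <- tracks[[first]]$freqs[1]
    f_end <- vapply(cand, function(i)
      tracks[[i]]$freqs[length(tracks[[i]]$freqs)], numeric(1))
    co <- order(abs(f_end - f_first), -dur[cand], -end[cand])
    selected <- c(cand[co[1]], selected)
  }
  selected <- selected[order(start[selected])]

  freq <- rep(NA_real_, n_slices)
  conf <- rep("gap-bridged", n_slices)
  for (i in selected) {
    tr <- tracks[[i]]
    span <- tr$start_slice:tr$end_slice
    span <- span[span >= 1 & span <= n_slices]
    if (length(tr$slices) >= 2) {
      freq[span] <- stats::approx(tr$slices, tr$freqs, xout = span,
                                  rule = 2)$y
    } else {
      freq[span] <- tr$freqs[1]
    }
    pk <- tr$slices[tr$slices >= 1 & tr$slices <= n_slices]
    conf[pk] <- "tracked"
  }
  if (anyNA(freq)) {
    known <- which(!is.na(freq))
    freq <- stats::approx(known, freq[known], xout = seq_len(n_slices),
                          method = "constant", f = 0, rule = 2)$y
  }
  list(freq_hz = freq, confidence = conf, selected = selected,
       winner = winner)
}

#' Spectral-continuity ECG-derived respiration (scEDR)
#'
#' The full extraction: per-slice significant peaks
#' ([extract_slice_peaks()]), greedy continuity linking into tracks
#' ([build_tracks()]), longest-track selection with apnea rejoining
#' ([select_breathing_track()]). Within the respiratory-effort band,
#' usually only one track — the RSA component — keeps smooth continuity
#' over prolonged periods; transient perturbations emerge and dissolve as
#' short-lived tracks and are ignored no matter how strong. The breathing
#' rate is 60 times the extracted frequency. Optionally the breathing
#' signal is reconstructed by the band-limited inverse transform around the
#' extracted frequency.
#'
#' @param map a [cwt_morse()] map covering the configured threshold band.
#' @param config a [scedr_config()].
#' @param reconstruct also reconstruct the breathing signal?
#' @param previous_track optional fallback track (see
#'   [select_breathing_track()]).
#' @return an `edr_result`: `br` (a [br_series()], source `"scedr"`),
#'   `freq_hz`, `tracks`, `selected`, `winner`, `reconstructed` (or `NULL`).
#' @export
scedr <- function(map, config = scedr_config(), reconstruct = FALSE,
                  previous_track = NULL) {
  if (min(map$freqs_hz) > config$threshold_band[1] + 1e-9 ||
        max(map$freqs_hz) < config$threshold_band[2] - 1e-9)
    stop("map does not cover the configured threshold band")
  peaks <- extract_slice_peaks(map, config$search_band,
                               config$threshold_band, config$threshold_frac)
  tracks <- build_tracks(peaks, config$link_tolerance_hz,
                         config$gap_tolerance_slices)
  sel <- select_breathing_track(tracks, nrow(map$coefficients),
                                previous_track,
                                config$rejoin_window_slices)
  br <- br_series(60 * sel$freq_hz, map$slice_times_s,
                  1 / map$slice_step_s, source = "scedr",
                  confidence = sel$confidence)
  recon <- if (reconstruct)
    inverse_cwt_band(map, sel$freq_hz, config$reconstruct_halfwidth_hz)
  else NULL
  structure(list(br = br, freq_hz = sel$freq_hz, tracks = tracks,
                 selected = sel$selected, winner = sel$winner,
                 reconstructed = recon),
            class = "edr_result")
}

#' Max-power EDR baseline
#'
#' Classical spectral baseline: in every slice the significant peak of
#' highest power inside the search band is taken as the breathing
#' frequency, with no continuity constraint. Slices with no significant
#' peak hold the previous frequency and are flagged `gap-bridged`.
#'
#' @inheritParams scedr
#' @return an `edr_result` with `br$source == "maxpower"` (`tracks`,
#'   `selected`, `winner` empty).
#' @export
maxpower_edr <- function(map, config = scedr_config()) {
  peaks <- extract_slice_peaks(map, config$search_band,
                               config$threshold_band, config$threshold_frac)
  ns <- nrow(map$coefficients)
  freq <- rep(NA_real_, ns)
  conf <- rep("gap-bridged", ns)
  if (nrow(peaks)) {
    best <- vapply(split(seq_len(nrow(peaks)), peaks$slice), function(rows)
      rows[which.max(peaks$power[rows])], integer(1))
    freq[peaks$slice[best]] <- peaks$freq_hz[best]
    conf[peaks$slice[best]] <- "tracked"
  }
  if (all(is.na(freq)))
    stop("no respiratory component: no significant peaks in the search band")
  known <- which(!is.na(freq))
  freq <- stats::approx(known, freq[known], xout = seq_len(ns),
                        method = "constant", f = 0, rule = 2)$y
  br <- br_series(60 * freq, map$slice_times_s, 1 / map$slice_step_s,
                  source = "maxpower", confidence = conf)
  structure(list(br = br, freq_hz = freq, tracks = list(),
                 selected = integer(0), winner = NA_integer_,
                 reconstructed = NULL),
            class = "edr_result")
}

#' @export
print.edr_result <- function(x, ...) {
  cat(sprintf("<edr_result:%s> %d slices, %d tracks, median BR %.1f bpm\n",
              x$br$source, length(x$freq_hz), length(x$tracks),
              stats::median(x$br$br_bpm)))
  invisible(x)
}
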