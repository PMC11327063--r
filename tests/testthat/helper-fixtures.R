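# Shared fixtures and independent oracles for the test suite.

# Independent longest-path oracle over the linking DAG. Edges run from a peak
# to the compatible peaks (|df| <= link_tol) of the FIRST later slice within
# the gap tolerance that contains any compatible peak -- the same "adjacent in
# time" relation the sequential linker uses. Dynamic programming over the
# earliest reachable start slice; exhaustive over all paths.
oracle_longest_duration <- function(peaks, link_tol, gap_tol) {
  n <- nrow(peaks)
  if (is.null(n) || n == 0) return(0L)
  peaks <- peaks[order(peaks$slice, peaks$freq_hz), , drop = FALSE]
  minstart <- peaks$slice
  for (i in seq_len(n)) {
    later <- sort(unique(peaks$slice[peaks$slice > peaks$slice[i] &
                                       peaks$slice - peaks$slice[i] - 1 <= gap_tol]))
    for (s2 in later) {
      cand <- which(peaks$slice == s2 &
                      abs(peaks$freq_hz - peaks$freq_hz[i]) <= link_tol + 1e-9)
      if (length(cand)) {
        minstart[cand] <- pmin(minstart[cand], minstart[i])
        break
      }
    }
  }
  max(peaks$slice - minstart + 1)
}

# Random peak grid in the linker's operating regime: one persistent ridge
# whose frequency drifts much slower than a bin per slice (with occasional
# dropouts), plus 0-2 transient peaks per slice offset at least 2 bins from
# the ridge neighbourhood. <= 12 slices x <= 5 peaks per slice, 21 bins.
random_peak_grid <- function() {
  ns <- sample(6:12, 1)
  nbins <- 21
  b <- sample(5:17, 1)
  rows <- list()
  for (s in seq_len(ns)) {
    if (stats::runif(1) < 0.2) b <- min(nbins - 2, max(3, b + sample(c(-1, 1), 1)))
    k <- sample(0:2, 1, prob = c(0.5, 0.3, 0.2))
    far <- setdiff(seq_len(nbins), (b - 2):(b + 2))
    fr <- if (stats::runif(1) < 0.9) b else integer(0)
    fr <- unique(c(fr, if (k > 0) sample(far, k)))
    if (length(fr))
      rows[[length(rows) + 1]] <- data.frame(
        slice = s, freq_hz = 0.03 + 0.02 * fr,
        power = stats::runif(length(fr), 0.5, 2))
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

# Permissive DAG (edges to ANY slice within the gap tolerance): a superset of
# every link the greedy can make, hence a valid upper bound on its duration.
oracle_upper_bound_duration <- function(peaks, link_tol, gap_tol) {
  n <- nrow(peaks)
  if (is.null(n) || n == 0) return(0L)
  peaks <- peaks[order(peaks$slice, peaks$freq_hz), , drop = FALSE]
  minstart <- peaks$slice
  for (i in seq_len(n)) {
    preds <- which(peaks$slice < peaks$slice[i] &
                     peaks$slice[i] - peaks$slice - 1 <= gap_tol &
                     abs(peaks$freq_hz - peaks$freq_hz[i]) <= link_tol + 1e-9)
    if (length(preds)) minstart[i] <- min(minstart[preds])
  }
  max(peaks$slice - minstart + 1)
}

# Deliberately adversarial grid: dense i.i.d. peaks on adjacent bins.
random_dense_grid <- function() {
  ns <- sample(4:12, 1)
  rows <- lapply(seq_len(ns), function(s) {
    k <- sample(0:5, 1)
    if (k == 0) return(NULL)
    bb <- sort(sample(15, k))
    data.frame(slice = s, freq_hz = 0.13 + 0.02 * bb,
               power = stats::runif(k, 0.5, 2))
  })
  do.call(rbind, rows)
}

# does the grid contain an equal-|df| linking ambiguity (two candidate peaks
# equidistant from a source peak, or two sources equidistant from a target)?
has_equal_df_tie <- function(peaks, link_tol, gap_tol) {
  n <- nrow(peaks)
  for (i in seq_len(n)) {
    later <- which(peaks$slice > peaks$slice[i] &
                     peaks$slice - peaks$slice[i] - 1 <= gap_tol)
    for (s2 in unique(peaks$slice[later])) {
      tg <- which(peaks$slice == s2 &
                    abs(peaks$freq_hz - peaks$freq_hz[i]) <= link_tol + 1e-9)
      d <- round(abs(peaks$freq_hz[tg] - peaks$freq_hz[i]), 9)
      if (anyDuplicated(d)) return(TRUE)
      sr <- which(peaks$slice == peaks$slice[i] &
                    abs(peaks$freq_hz - peaks$freq_hz[tg[1]]) <= link_tol + 1e-9)
      if (length(tg) && length(sr) > 1) {
        d2 <- round(abs(peaks$freq_hz[sr] - peaks$freq_hz[tg[1]]), 9)
        if (anyDuplicated(d2)) return(TRUE)
      }
    }
  }
  FALSE
}

longest_greedy_duration <- function(peaks, link_tol, gap_tol) {
  tr <- build_tracks(peaks, link_tol, gap_tol)
  if (!length(tr)) 0L else max(vapply(tr, `[[`, integer(1), "duration_slices"))
}

# Reference scenarios ---------------------------------------------------------

# quiet constant breathing, no disturbances: the single-tone calibration case
scenario_constant <- function(duration_s = 600, br = 15, seed = 11,
                              rsa = 2, hr0 = 70) {
  sim_scenario(duration_s = duration_s, hr_baseline = hr0, rsa_amplitude = rsa,
               br_trajectory = br, lf_noise_amp = 0, seed = seed)
}

# plateau - linear ramp - plateau breathing trajectory
scenario_ramp <- function(plateau_s = 300, ramp_s = 1200,
                          br_from = 12, br_to = 20, seed = 12) {
  knots <- data.frame(
    time_s = c(0, plateau_s, plateau_s + ramp_s, 2 * plateau_s + ramp_s),
    br_bpm = c(br_from, br_from, br_to, br_to))
  sim_scenario(duration_s = 2 * plateau_s + ramp_s, br_trajectory = knots,
               lf_noise_amp = 0, seed = seed)
}

# transient interferer against constant breathing; amp_factor is relative to
# the RSA amplitude (sqrt(2) = twice the RSA power)
scenario_interferer <- function(duration_s = 600, br = 15,
                                int_start = 285, int_stop = 315,
                                int_freq = 0.35, amp_factor = sqrt(2),
                                seed = 13) {
  sim_scenario(duration_s = duration_s, rsa_amplitude = 2, br_trajectory = br,
               interferers = data.frame(start_s = int_start, stop_s = int_stop,
                                        freq_hz = int_freq,
                                        amplitude_bpm = 2 * amp_factor),
               lf_noise_amp = 0, seed = seed)
}

uniform_hypnogram <- function(duration_s, label = "N2", epoch_s = 30) {
  hypnogram(rep(label, floor(duration_s / epoch_s)), epoch_s = epoch_s)
}

# epoch means of a series restricted to 30-s hypnogram epochs
epoch_means <- function(x, times_s, hypno) {
  vapply(seq_len(nrow(hypno)), function(i) {
    s0 <- hypno$epoch_start_s[i]
    mean(x[times_s >= s0 & times_s < s0 + attr(hypno, "epoch_s")], na.rm = TRUE)
  }, numeric(1))
}
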