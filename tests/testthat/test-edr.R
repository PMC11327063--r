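# minimal hand-built map for slice-level tests
fake_map <- function(power, freqs) {
  structure(list(power = power, freqs_hz = freqs,
                 coi_invalid = matrix(FALSE, nrow(power), ncol(power)),
                 coefficients = matrix(complex(real = sqrt(power)),
                                       nrow(power), ncol(power)),
                 slice_times_s = (seq_len(nrow(power)) - 1) * 0.05,
                 slice_step_s = 0.05, input_fs = 20,
                 filter_energy = rep(1, length(freqs)),
                 params = morse_params()),
            class = "tfa_map")
}

test_that("slice peaks obey the 20% dynamic threshold", {
  f <- seq(0.15, 0.23, by = 0.02)
  m <- fake_map(matrix(c(1, 5, 2, 8, 3), nrow = 1), f)
  pk <- extract_slice_peaks(m, search_band = c(0.15, 0.23),
                            threshold_band = c(0.15, 0.23), edge_buffer_s = 0)
  expect_equal(pk$freq_hz, c(f[2], f[4]))
  expect_equal(pk$power, c(5, 8))

  m2 <- fake_map(matrix(c(1, 1.5, 1, 10, 1), nrow = 1), f)
  pk2 <- extract_slice_peaks(m2, search_band = c(0.15, 0.23),
                             threshold_band = c(0.15, 0.23), edge_buffer_s = 0)
  expect_equal(pk2$freq_hz, f[4])    # 1.5 < 0.2 * 10 drops the first maximum

  m3 <- fake_map(matrix(0, nrow = 2, ncol = 5), f)
  expect_equal(nrow(extract_slice_peaks(m3, c(0.15, 0.23), c(0.15, 0.23),
                                         edge_buffer_s = 0)), 0)

  expect_error(extract_slice_peaks(m, search_band = c(0.15, 0.23),
                                   threshold_band = c(0.17, 0.23)),
               "must contain")
})

test_that("wider-spectrum threshold suppresses weak breathing-band peaks", {
  # strong slow component at 0.05 Hz dominates the threshold band: a small
  # 0.25 Hz bump below 20% of it is insignificant
  f <- seq(0.05, 0.45, by = 0.02)
  p <- rep(0.001, length(f))
  p[f == 0.05] <- 10
  p[f == 0.25] <- 1.5
  pk <- extract_slice_peaks(fake_map(matrix(p, nrow = 1), f), edge_buffer_s = 0)
  expect_equal(nrow(pk), 0)
  p[f == 0.25] <- 2.5                 # above 0.2 * 10: survives
  pk2 <- extract_slice_peaks(fake_map(matrix(p, nrow = 1), f), edge_buffer_s = 0)
  expect_equal(pk2$freq_hz, 0.25)
})

test_that("tracks form from temporally adjacent similar-frequency peaks", {
  pk <- data.frame(slice = 1:100, freq_hz = 0.25, power = 1)
  tr <- build_tracks(pk, 0.02, 40L)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$duration_slices, 100L)

  pk2 <- rbind(pk, data.frame(slice = 40:60, freq_hz = 0.35, power = 2))
  tr2 <- build_tracks(pk2, 0.02, 40L)
  expect_length(tr2, 2)
  expect_setequal(vapply(tr2, `[[`, integer(1), "duration_slices"),
                  c(100L, 21L))
})

test_that("greedy linking equals the DAG longest path in the operating regime", {
  set.seed(42)
  matches <- 0L
  for (g in 1:100) {
    peaks <- random_peak_grid()
    if (is.null(peaks)) { matches <- matches + 1L; next }
    gl <- longest_greedy_duration(peaks, 0.02, 2L)
    if (gl == oracle_longest_duration(peaks, 0.02, 2L)) matches <- matches + 1L
  }
  expect_gte(matches, 95)
})

test_that("greedy never exceeds the oracle, even on dense adversarial grids", {
  set.seed(43)
  for (g in 1:50) {
    peaks <- random_dense_grid()
    if (is.null(peaks)) next
    expect_lte(longest_greedy_duration(peaks, 0.02, 2L),
               oracle_upper_bound_duration(peaks, 0.02, 2L))
  }
})

test_that("track selection prefers duration, then mean power", {
  pk <- rbind(data.frame(slice = 1:100, freq_hz = 0.25, power = 1),
              data.frame(slice = 40:60, freq_hz = 0.35, power = 5))
  tr <- build_tracks(pk, 0.02, 40L)
  sel <- select_breathing_track(tr, 100)
  expect_equal(unique(sel$freq_hz), 0.25)

  pk2 <- rbind(data.frame(slice = 1:50, freq_hz = 0.21, power = 3.0),
               data.frame(slice = 1:50, freq_hz = 0.41, power = 1.2))
  tr2 <- build_tracks(pk2, 0.02, 40L)
  sel2 <- select_breathing_track(tr2, 50)
  expect_equal(unique(sel2$freq_hz), 0.21)   # equal duration: higher power wins
})

test_that("a broken breathing track rejoins the nearest-frequency candidate", {
  # gap tolerance below the 39-slice dropout, so the 0.27 Hz candidate is a
  # separate track and selection has to bridge and rejoin
  pk <- rbind(data.frame(slice = 1:200, freq_hz = 0.26, power = 1),
              data.frame(slice = 240:280, freq_hz = 0.27, power = 1),
              data.frame(slice = 240:260, freq_hz = 0.40, power = 1))
  tr <- build_tracks(pk, 0.02, 20L)
  sel <- select_breathing_track(tr, 280, rejoin_window_slices = 1200L)
  expect_equal(sel$freq_hz[1:200], rep(0.26, 200))
  expect_equal(sel$freq_hz[201:239], rep(0.26, 39))           # held
  expect_true(all(sel$confidence[201:239] == "gap-bridged"))
  expect_equal(sel$freq_hz[240:280], rep(0.27, 41))           # rejoined
  expect_true(all(sel$confidence[240:280] == "tracked"))
  expect_error(select_breathing_track(list(), 10), "no respiratory component")
})

test_that("scEDR follows the persistent RSA track through an interferer", {
  sc <- scenario_interferer()
  sim <- simulate_heart_rate(sc)
  m <- tfa_heart_rate(sim$hr)
  res <- scedr(m)
  mp <- maxpower_edr(m)

  during <- m$slice_times_s >= 287 & m$slice_times_s <= 313
  expect_lt(max(abs(res$br$br_bpm[during] - 15)), 1.2)
  expect_gt(max(abs(mp$br$br_bpm[during] - 15)), 3)   # baseline jumps away

  # continuity invariant on tracked slices; the baseline violates it
  tracked <- res$br$confidence == "tracked"
  jumps <- abs(diff(res$freq_hz))[tracked[-1] & tracked[-length(tracked)]]
  expect_lte(max(jumps), 0.02 + 1e-9)
  mp_jumps <- abs(diff(mp$freq_hz))
  expect_gt(max(mp_jumps), 0.02 + 1e-9)
})

test_that("without interference scEDR and Max-Power agree; error shrinks with interferer amplitude", {
  amps <- c(2 * sqrt(2), 1.0, 0)
  errs_sc <- errs_mp <- numeric(length(amps))
  for (i in seq_along(amps)) {
    sc <- if (amps[i] > 0)
      sim_scenario(duration_s = 300, rsa_amplitude = 2, br_trajectory = 15,
                   interferers = data.frame(start_s = 135, stop_s = 165,
                                            freq_hz = 0.35,
                                            amplitude_bpm = amps[i]),
                   lf_noise_amp = 0, seed = 14)
    else
      sim_scenario(duration_s = 300, rsa_amplitude = 2, br_trajectory = 15,
                   lf_noise_amp = 0, seed = 14)
    sim <- simulate_heart_rate(sc)
    m <- tfa_heart_rate(sim$hr)
    errs_sc[i] <- mean(abs(scedr(m)$br$br_bpm - 15))
    errs_mp[i] <- mean(abs(maxpower_edr(m)$br$br_bpm - 15))
  }
  expect_true(all(diff(errs_sc) <= 1e-9))   # non-increasing as amplitude -> 0
  expect_equal(errs_sc[3], errs_mp[3])      # identical when nothing interferes
})

test_that("maxpower follows power, not continuity, on a two-tone map", {
  t <- seq(0, 600 - 0.05, by = 0.05)
  x <- cos(2 * pi * 0.25 * t)
  m <- cwt_morse(x, tfa_frequency_grid(), sample_rate_hz = 20)
  mp <- maxpower_edr(m)
  expect_equal(unique(mp$br$br_bpm), 15)

  x2 <- cos(2 * pi * 0.21 * t) + 2 * cos(2 * pi * 0.41 * t)
  m2 <- cwt_morse(x2, tfa_frequency_grid(), sample_rate_hz = 20)
  mp2 <- maxpower_edr(m2)
  interior <- !apply(m2$coi_invalid, 1, any)
  expect_true(all(mp2$br$br_bpm[interior] == 60 * 0.41))
})

test_that("extracted rate stays inside the 9-27 bpm band", {
  for (seed in 15:17) {
    sc <- sim_scenario(duration_s = 240, br_trajectory = 15 + (seed - 15) * 4,
                       noise_sd_bpm = 0.5, seed = seed)
    sim <- simulate_heart_rate(sc)
    res <- scedr(tfa_heart_rate(sim$hr))
    expect_true(all(res$br$br_bpm >= 9 & res$br$br_bpm <= 27))
  }
})
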