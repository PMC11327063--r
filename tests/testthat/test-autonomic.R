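test_that("single tones land their power in the right HRV band", {
  t <- seq(0, 600 - 0.05, by = 0.05)
  hy <- uniform_hypnogram(600)
  m_lf <- cwt_morse(2 * cos(2 * pi * 0.10 * t), hrv_frequency_grid(),
                    sample_rate_hz = 20)
  bp_lf <- band_powers(m_lf, hy)
  ok <- bp_lf$valid
  expect_gt(stats::median(bp_lf$lf_hf_ratio[ok]), 10)

  m_hf <- cwt_morse(2 * cos(2 * pi * 0.25 * t), hrv_frequency_grid(),
                    sample_rate_hz = 20)
  bp_hf <- band_powers(m_hf, hy)
  expect_lt(stats::median(bp_hf$lf_hf_ratio[bp_hf$valid]), 0.1)
})

test_that("band powers are additive over the non-overlapping bands", {
  set.seed(51)
  m <- cwt_morse(rnorm(6000), hrv_frequency_grid(), sample_rate_hz = 20)
  hy <- uniform_hypnogram(300)
  bp <- band_powers(m, hy)
  psd <- tfa_psd(m)
  f <- m$freqs_hz
  tt <- m$slice_times_s
  tz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  for (i in which(bp$valid)[1:3]) {
    ctr <- hy$epoch_start_s[i] + 15
    sel <- tt >= ctr - 45 & tt < ctr + 45
    mp <- colMeans(psd[sel, ])
    bins <- f >= 0.004 & f <= 0.40
    total <- tz(f[bins], mp[bins])
    expect_equal(bp$vlf_power[i] + bp$lf_power[i] + bp$hf_power[i], total,
                 tolerance = 1e-9)
  }
  # epochs whose 90-s window leaves the record are flagged
  expect_false(bp$valid[1])
  expect_false(bp$valid[nrow(bp)])
})

test_that("white-noise LF/HF approaches the bandwidth ratio", {
  set.seed(52)
  lf <- hf <- numeric(20)
  for (i in 1:20) {
    m <- cwt_morse(rnorm(6000), hrv_frequency_grid(), sample_rate_hz = 20)
    bp <- band_powers(m, uniform_hypnogram(300))
    lf[i] <- mean(bp$lf_power[bp$valid])
    hf[i] <- mean(bp$hf_power[bp$valid])
  }
  expect_equal(mean(lf) / mean(hf), 0.10 / 0.25, tolerance = 0.12)
})

test_that("epoch variability matches closed forms", {
  hy <- uniform_hypnogram(120)
  t <- seq(0, 120 - 0.05, by = 0.05)
  v0 <- variability_per_epoch(rep(60, length(t)), hy, times_s = t)
  expect_true(all(v0$variability == 0))

  x <- 60 + 5 * sin(2 * pi * t / 30)      # whole cycles per epoch
  v <- variability_per_epoch(x, hy, times_s = t)
  expect_equal(v$variability, rep(5 / sqrt(2), 4), tolerance = 0.01)

  # stage-programmed RSA depth ranks the per-epoch variability
  sc <- sim_scenario(duration_s = 90, rsa_amplitude = 1, br_trajectory = 15,
                     lf_noise_amp = 0, seed = 53)
  sc2 <- sim_scenario(duration_s = 90, rsa_amplitude = 4, br_trajectory = 15,
                      lf_noise_amp = 0, seed = 53)
  hy3 <- uniform_hypnogram(90)
  vlo <- variability_per_epoch(simulate_heart_rate(sc)$hr, hy3)
  vhi <- variability_per_epoch(simulate_heart_rate(sc2)$hr, hy3)
  expect_true(all(vhi$variability > vlo$variability))
})

test_that("thresholds derive from the eyes-closed baseline", {
  hy <- hypnogram(c(rep("ECW", 4), rep("N2", 4)))
  hv <- data.frame(epoch_index = 1:8, label = hy$label,
                   variability = c(1, 1, 1, 1, 5, 5, 5, 5), valid = TRUE)
  th <- derive_thresholds(hv, NULL, hy)
  expect_equal(th$hr_var_threshold, 1)
  expect_equal(th$baseline_epochs, 1:4)

  hy100 <- hypnogram(rep("ECW", 100))
  hv100 <- data.frame(epoch_index = 1:100, label = "ECW",
                      variability = 1:100, valid = TRUE)
  expect_equal(derive_thresholds(hv100, NULL, hy100)$hr_var_threshold, 95,
               tolerance = 0.5)
  expect_error(derive_thresholds(hv, NULL, hypnogram(rep("N2", 8))), "no ECW")
})

test_that("REM0 reassignment implements the three-branch rule", {
  hy <- hypnogram(c("N2", "N3", "N2"))
  hv <- data.frame(epoch_index = 1:3, label = hy$label,
                   variability = c(1, 3, 3), valid = TRUE)
  gv <- data.frame(epoch_index = 1:3, label = hy$label,
                   variability = c(9, 5, 1), valid = TRUE)
  th <- structure(list(hr_var_threshold = 2, gfp_var_threshold = 4,
                       baseline_epochs = integer(0), prob = 0.95),
                  class = "variability_thresholds")
  out <- reassign_rem0(hy, hv, gv, th)
  expect_equal(out$label, c("N2", "REM0", "REM"))
  expect_equal(out$label_expert, c("N2", "N3", "N2"))
  expect_equal(out$reassigned, c(FALSE, TRUE, TRUE))
})

test_that("epochs below the HR threshold are never altered", {
  set.seed(54)
  th <- structure(list(hr_var_threshold = 2, gfp_var_threshold = 4,
                       baseline_epochs = integer(0), prob = 0.95),
                  class = "variability_thresholds")
  for (i in 1:200) {
    n <- sample(5:40, 1)
    labs <- sample(c("ECW", "N1", "N2", "N3", "REM"), n, replace = TRUE)
    hy <- hypnogram(labs)
    hv <- data.frame(epoch_index = 1:n, label = labs,
                     variability = runif(n, 0, 4), valid = TRUE)
    gv <- data.frame(epoch_index = 1:n, label = labs,
                     variability = runif(n, 0, 8), valid = TRUE)
    out <- reassign_rem0(hy, hv, gv, th)
    cold <- hv$variability <= th$hr_var_threshold
    expect_identical(out$label[cold], labs[cold])
    expect_true(all(out$label[!cold] %in% c("REM", "REM0")))
  }
})

test_that("missing GFP leaves hot epochs unresolved with the expert label", {
  hy <- hypnogram(c("N2", "N2"))
  hv <- data.frame(epoch_index = 1:2, label = hy$label,
                   variability = c(3, 1), valid = TRUE)
  gv <- data.frame(epoch_index = 1:2, label = hy$label,
                   variability = c(NA, NA), valid = FALSE)
  th <- structure(list(hr_var_threshold = 2, gfp_var_threshold = 4,
                       baseline_epochs = integer(0), prob = 0.95),
                  class = "variability_thresholds")
  out <- reassign_rem0(hy, hv, gv, th)
  expect_equal(out$label, c("N2", "N2"))
  expect_equal(attr(out, "unresolved"), 1L)
})

test_that("GFP is the across-channel SD", {
  set.seed(55)
  eeg <- matrix(rnorm(50 * 6), 50, 6)
  expect_equal(gfp(eeg), apply(eeg, 1, sd))
  expect_error(gfp(eeg[, 1, drop = FALSE]), "2 channels")
})
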