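mk_br <- function(values, source = "pressure", dur = 120, rate = 20,
                  confidence = "tracked") {
  t <- seq(0, dur - 1e-9, by = 1 / rate)
  br_series(rep_len(values, length(t)), t, rate, source = source,
            confidence = confidence)
}

test_that("epoch error and %error follow their defining formulas", {
  hy <- uniform_hypnogram(120)
  tab <- epoch_errors(mk_br(15.5, "scedr"), mk_br(15.0), hy)
  expect_equal(tab$error_bpm, rep(0.5, 4))
  expect_equal(tab$pct_error, rep(100 * 0.5 / 15, 4))
  expect_equal(tab$method[1], "scedr")

  same <- epoch_errors(mk_br(12, "scedr"), mk_br(12), hy)
  expect_true(all(same$error_bpm == 0) && all(same$pct_error == 0))
})

test_that("%error is invariant to common rescaling of both series", {
  hy <- uniform_hypnogram(120)
  set.seed(61)
  v1 <- runif(4, 12, 20)
  a <- mk_br(rep(v1, each = 600), "scedr")
  b <- mk_br(15)
  t1 <- epoch_errors(a, b, hy)
  a2 <- a; a2$br_bpm <- 1.3 * a2$br_bpm
  b2 <- b; b2$br_bpm <- 1.3 * b2$br_bpm
  t2 <- epoch_errors(a2, b2, hy)
  expect_equal(t1$pct_error, t2$pct_error, tolerance = 1e-12)
})

test_that("mismatched grids are rejected; empty epochs are dropped with a log", {
  hy <- uniform_hypnogram(120)
  short <- mk_br(15, "scedr", dur = 60)
  expect_error(epoch_errors(short, mk_br(15), hy), "share one uniform grid")

  edr <- mk_br(15, "scedr")
  edr$br_bpm[1201:1800] <- NA                     # epoch 3 has no usable data
  expect_message(tab <- epoch_errors(edr, mk_br(15), hy), "epoch 3")
  expect_equal(tab$epoch_index, c(1, 2, 4))
})

test_that("gap-bridged samples can be excluded from epoch means", {
  hy <- uniform_hypnogram(60)
  # alternate tracked samples at the true rate with bridged samples held high
  conf <- rep(c("tracked", "gap-bridged"), 600)
  vals <- rep(c(15, 21), 600)
  edr <- mk_br(vals, "scedr", dur = 60, confidence = conf)
  with_b <- epoch_errors(edr, mk_br(15, dur = 60), hy)
  without_b <- epoch_errors(edr, mk_br(15, dur = 60), hy,
                            include_bridged = FALSE)
  expect_equal(with_b$error_bpm, c(3, 3))
  expect_equal(without_b$error_bpm, c(0, 0))
})

test_that("stage summaries aggregate correctly and weight back to the whole record", {
  hy <- hypnogram(c("N2", "N2", "N3", "REM"))
  edr <- mk_br(rep(c(16, 18, 12, 13), each = 600), "scedr")
  tab <- epoch_errors(edr, mk_br(15), hy)
  sm <- stage_summary(tab)
  n2 <- sm[sm$stage == "N2", ]
  expect_equal(n2$mean_error, 2)
  expect_equal(n2$sd_error, sqrt(2))
  expect_equal(n2$n_epochs, 2)
  whole <- sm[sm$stage == "whole record", ]
  per_stage <- sm[sm$stage != "whole record", ]
  expect_equal(sum(per_stage$mean_error * per_stage$n_epochs) /
                 sum(per_stage$n_epochs), whole$mean_error)
  expect_false("N1" %in% sm$stage)
})

test_that("with stage-dependent interference the REM-like error dominates", {
  sc <- sim_scenario(
    duration_s = 360, rsa_amplitude = 2, br_trajectory = 15,
    interferers = data.frame(start_s = c(250, 300), stop_s = c(280, 330),
                             freq_hz = c(0.35, 0.40),
                             amplitude_bpm = c(4, 4)),
    lf_noise_amp = 0, seed = 62)
  sim <- simulate_heart_rate(sc)
  fl <- simulate_flow(sim$truth, sc)
  brp <- br_from_flow(fl, duration_s = sc$duration_s)
  m <- tfa_heart_rate(sim$hr)
  hy <- hypnogram(c(rep("N3", 8), rep("REM", 4)))   # interferers live in REM
  tab_mp <- epoch_errors(maxpower_edr(m)$br, brp, hy)
  sm <- stage_summary(tab_mp)
  expect_gt(sm$mean_pct_error[sm$stage == "REM"],
            sm$mean_pct_error[sm$stage == "N3"])
})

test_that("the whole-record report renders four aligned panels and CSVs", {
  sc <- scenario_constant(duration_s = 120, seed = 63)
  sim <- simulate_heart_rate(sc)
  fl <- simulate_flow(sim$truth, sc)
  brp <- br_from_flow(fl, duration_s = 120)
  res <- scedr(tfa_heart_rate(sim$hr))
  hy <- hypnogram(c("ECW", "N2", "REM", "N2"))
  tab <- epoch_errors(res$br, brp, hy)

  td <- tempfile()
  png_file <- file.path(tempdir(), "report.png")
  paths <- whole_record_report(sim$hr, res$br, brp, hy, tab,
                               file = png_file, csv_dir = td)
  expect_true(file.exists(png_file))
  expect_true(all(file.exists(file.path(td, c("hr.csv", "br.csv",
                                              "epoch_errors.csv")))))
  br_out <- utils::read.csv(file.path(td, "br.csv"))
  expect_equal(nrow(br_out), length(sim$hr$times_s))  # shared time axis
})
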