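#' Standard HRV frequency bands
#'
#' VLF 0.004-0.05 Hz, LF 0.05-0.15 Hz, HF 0.15-0.40 Hz. LF power is
#' commonly read as sympathetically driven and HF as parasympathetic
#' (respiration is the dominant HF contributor), so LF/HF indexes autonomic
#' balance.
#'
#' @return named list of `c(lo, hi)` band edges in Hz.
#' @export
band_definition <- function() {
  list(vlf = c(0.004, 0.05), lf = c(0.05, 0.15), hf = c(0.15, 0.40))
}

#' Frequency grid for HRV band analysis
#'
#' Extended grid covering 0.004-0.45 Hz with every band edge included, so
#' band integrals are additive by construction: 0.002-Hz steps through the
#' VLF band, 0.005-Hz steps above it.
#'
#' @return numeric vector of frequencies, Hz.
#' @export
hrv_frequency_grid <- function() {
  c(seq(0.004, 0.05, by = 0.002), seq(0.055, 0.45, by = 0.005))
}

trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Per-epoch HRV band powers and ratios
#'
#' For every 30-s epoch, the PSD estimate ([tfa_psd()]) is averaged over a
#' 90-s window centered on the epoch and integrated over each band
#' (trapezoid over the bin frequencies). VLF periods reach 250 s, so VLF
#' values from 90-s windows are partial-cycle estimates; they are reported
#' as such, not windowed further. Epochs whose 90-s window leaves the
#' record are flagged invalid and excluded from summaries.
#'
#' @param map a [cwt_morse()] map whose grid covers 0.004-0.40 Hz (see
#'   [hrv_frequency_grid()]).
#' @param hypno a [hypnogram()].
#' @param bands band edges, as [band_definition()].
#' @param window_s spectral averaging window, seconds.
#' @return data frame: `epoch_index`, `label`, `vlf_power`, `lf_power`,
#'   `hf_power` (units bpm^2), `lf_hf_ratio`, `vlf_hf_ratio`, `valid`.
#'   Ratios are `NA` when HF power is zero.
#' @export
band_powers <- function(map, hypno, bands = band_definition(),
                        window_s = 90) {
  if (min(map$freqs_hz) > bands$vlf[1] + 1e-9 ||
        max(map$freqs_hz) < bands$hf[2] - 1e-9)
    stop("map grid does not cover the requested bands; use hrv_frequency_grid()")
  psd <- tfa_psd(map)
  tt <- map$slice_times_s
  epoch_s <- attr(hypno, "epoch_s")
  f <- map$freqs_hz
  bins <- lapply(bands, function(b) which(f >= b[1] - 1e-9 & f <= b[2] + 1e-9))

  res <- lapply(seq_len(nrow(hypno)), function(i) {
    ctr <- hypno$epoch_start_s[i] + epoch_s / 2
    lo <- ctr - window_s / 2
    hi <- ctr + window_s / 2
    valid <- lo >= min(tt) - 1e-9 && hi <= max(tt) + 1e-9
    sel <- tt >= lo & tt < hi
    if (!valid || !any(sel))
      return(data.frame(epoch_index = i, label = hypno$label[i],
                        vlf_power = NA_real_, lf_power = NA_real_,
                        hf_power = NA_real_, lf_hf_ratio = NA_real_,
                        vlf_hf_ratio = NA_real_, valid = FALSE))
    mp <- colMeans(psd[sel, , drop = FALSE])
    pw <- vapply(bins, function(b) trapz(f[b], mp[b]), numeric(1))
    data.frame(epoch_index = i, label = hypno$label[i],
               vlf_power = pw[["vlf"]], lf_power = pw[["lf"]],
               hf_power = pw[["hf"]],
               lf_hf_ratio = if (pw[["hf"]] > 0) pw[["lf"]] / pw[["hf"]] else NA_real_,
               vlf_hf_ratio = if (pw[["hf"]] > 0) pw[["vlf"]] / pw[["hf"]] else NA_real_,
               valid = TRUE)
  })
  do.call(rbind, res)
}

#' Within-epoch variability of a uniformly sampled series
#'
#' Reference variability statistic: the standard deviation of the series
#' inside each 30-s epoch. Used both for heart-rate variability and for
#' EEG Global Field Power variability in the REM0 reassignment. Epochs with
#' more than half their samples missing are flagged invalid.
#'
#' @param x an [hr_series()] or numeric vector.
#' @param hypno a [hypnogram()].
#' @param times_s sample times when `x` is a bare vector.
#' @param stat the statistic, default [stats::sd()].
#' @return data frame: `epoch_index`, `label`, `variability`, `valid`.
#' @export
variability_per_epoch <- function(x, hypno, times_s = NULL, stat = stats::sd) {
  if (inherits(x, "hr_series")) {
    times_s <- x$times_s
    x <- x$hr_bpm
  }
  if (is.null(times_s)) stop("times_s required for a bare vector")
  k <- epoch_of_times(times_s, hypno)
  out <- data.frame(epoch_index = seq_len(nrow(hypno)),
                    label = hypno$label,
                    variability = NA_real_, valid = FALSE)
  for (i in seq_len(nrow(hypno))) {
    v <- x[!is.na(k) & k == i]
    if (length(v) >= 2 && mean(is.na(v)) <= 0.5) {
      out$variability[i] <- stat(v[!is.na(v)])
      out$valid[i] <- TRUE
    }
  }
  out
}

#' Global Field Power of multichannel EEG
#'
#' The across-channel spatial standard deviation at each time sample — the
#' standard GFP definition.
#'
#' @param eeg numeric matrix, rows = time samples, columns = channels.
#' @return numeric vector, one GFP value per sample.
#' @export
gfp <- function(eeg) {
  eeg <- as.matrix(eeg)
  if (ncol(eeg) < 2) stop("GFP needs at least 2 channels")
  apply(eeg, 1, stats::sd)
}

#' Variability thresholds from the pre-sleep eyes-closed baseline
#'
#' Thresholds for the REM0 reassignment are derived exclusively from the
#' eyes-closed awake (`ECW`) epochs before sleep onset: the configurable
#' percentile (default 95th) of the ECW-epoch variability, separately for
#' heart rate and GFP.
#'
#' @param hr_var data frame from [variability_per_epoch()] on heart rate.
#' @param gfp_var same, on the GFP series; `NULL` if unavailable.
#' @param hypno a [hypnogram()] (supplies the ECW epochs).
#' @param prob percentile used as threshold.
#' @return object of class `variability_thresholds`: `hr_var_threshold`,
#'   `gfp_var_threshold` (`NA` without GFP), `baseline_epochs`, `prob`.
#' @export
derive_thresholds <- function(hr_var, gfp_var = NULL, hypno, prob = 0.95) {
  ecw <- which(hypno$label == "ECW")
  if (!length(ecw))
    stop("no ECW epochs: thresholds cannot be defined")
  if (length(ecw) < 4)
    warning("fewer than 4 ECW baseline epochs; thresholds may be unstable")
  hv <- hr_var$variability[ecw]
  hv <- hv[is.finite(hv)]
  if (!length(hv)) stop("no valid ECW heart-rate variability values")
  thr_hr <- stats::quantile(hv, prob, names = FALSE)
  thr_gfp <- NA_real_
  if (!is.null(gfp_var)) {
    gv <- gfp_var$variability[ecw]
    gv <- gv[is.finite(gv)]
    if (length(gv)) thr_gfp <- stats::quantile(gv, prob, names = FALSE)
  }
  structure(list(hr_var_threshold = thr_hr, gfp_var_threshold = thr_gfp,
                 baseline_epochs = ecw, prob = prob),
            class = "variability_thresholds")
}

#' Reassign epochs to the putative REM0 stage
#'
#' Epoch rule: heart-rate variability at or below its threshold keeps the
#' expert label (whatever the GFP does); above the threshold, high GFP
#' variability reclassifies the epoch as `REM0` and low GFP variability as
#' `REM`. Epochs that would need a GFP decision but have none are flagged
#' unresolved and keep the expert label.
#'
#' @param hypno a [hypnogram()] with the expert labels.
#' @param hr_var,gfp_var data frames from [variability_per_epoch()].
#' @param thresholds a [derive_thresholds()] object.
#' @return a [hypnogram()] with updated `label`, the original labels in
#'   `label_expert`, a logical `reassigned` column, and the indices of
#'   unresolved epochs in attribute `unresolved`.
#' @export
reassign_rem0 <- function(hypno, hr_var, gfp_var, thresholds) {
  stopifnot(nrow(hr_var) == nrow(hypno))
  hv <- hr_var$variability
  gv <- if (is.null(gfp_var)) rep(NA_real_, nrow(hypno)) else gfp_var$variability
  stopifnot(length(gv) == nrow(hypno))

  out <- hypno
  out$label_expert <- hypno$label
  out$reassigned <- FALSE
  unresolved <- integer(0)
  hot <- !is.na(hv) & hv > thresholds$hr_var_threshold
  for (i in which(hot)) {
    if (is.na(gv[i]) || is.na(thresholds$gfp_var_threshold)) {
      unresolved <- c(unresolved, i)
    } else if (gv[i] > thresholds$gfp_var_threshold) {
      out$label[i] <- "REM0"
      out$reassigned[i] <- TRUE
    } else {
      out$label[i] <- "REM"
      out$reassigned[i] <- TRUE
    }
  }
  attr(out, "unresolved") <- unresolved
  attr(out, "epoch_s") <- attr(hypno, "epoch_s")
  class(out) <- class(hypno)
  out
}
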