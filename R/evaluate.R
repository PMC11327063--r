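#' Epoch-wise error of an extracted breathing rate against the gold standard
#'
#' Both series are averaged over each 30-s epoch; the absolute distance of
#' the two epoch means is the error in breaths per minute, and the error
#' divided by the gold-standard mean times 100 is the percentage error:
#' \deqn{\%Error = 100 \times |BR_{EDR} - BR_{pressure}| / BR_{pressure}}
#'
#' Gap-bridged (low-confidence) samples of the extracted series are
#' included by default — robustness during dropouts is part of what the
#' evaluation measures — but can be excluded. Epochs with no usable sample
#' in either series are dropped with a log line.
#'
#' @param br_edr extracted [br_series()] (`scedr` or `maxpower`).
#' @param br_pressure gold-standard [br_series()] (`pressure`), on the same
#'   grid.
#' @param hypno a [hypnogram()] covering the record.
#' @param include_bridged include gap-bridged samples in epoch means?
#' @return a `stage_epoch_table` data frame: `epoch_index`, `label`,
#'   `br_edr_mean`, `br_pressure_mean`, `error_bpm`, `pct_error`, `method`.
#' @export
epoch_errors <- function(br_edr, br_pressure, hypno, include_bridged = TRUE) {
  if (length(br_edr$br_bpm) != length(br_pressure$br_bpm) ||
        max(abs(br_edr$times_s - br_pressure$times_s)) > 1e-6)
    stop("the two breathing-rate series must share one uniform grid")
  k <- epoch_of_times(br_edr$times_s, hypno)
  x <- br_edr$br_bpm
  if (!include_bridged) x[br_edr$confidence == "gap-bridged"] <- NA_real_
  y <- br_pressure$br_bpm

  rows <- lapply(seq_len(nrow(hypno)), function(i) {
    sel <- !is.na(k) & k == i
    xv <- x[sel]; yv <- y[sel]
    if (!any(sel) || all(is.na(xv)) || all(is.na(yv))) {
      message(sprintf("epoch %d (%s) excluded: no usable samples", i,
                      hypno$label[i]))
      return(NULL)
    }
    mx <- mean(xv, na.rm = TRUE)
    my <- mean(yv, na.rm = TRUE)
    err <- abs(mx - my)
    data.frame(epoch_index = i, label = hypno$label[i],
               br_edr_mean = mx, br_pressure_mean = my,
               error_bpm = err, pct_error = 100 * err / my)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no epochs with usable samples")
  out$method <- br_edr$source
  class(out) <- c("stage_epoch_table", "data.frame")
  out
}

#' Stage-stratified error summary
#'
#' Mean and SD of the error and percentage error per sleep stage, plus a
#' whole-record row, with the number of contributing epochs. Stages present
#' in the hypnogram but contributing no epochs are reported in a log line
#' and omitted.
#'
#' @param table a [epoch_errors()] table.
#' @return data frame: `stage`, `mean_error`, `sd_error`, `mean_pct_error`,
#'   `sd_pct_error`, `n_epochs`, `method`.
#' @export
stage_summary <- function(table) {
  stopifnot(nrow(table) > 0)
  one <- function(stage, rows) {
    data.frame(stage = stage,
               mean_error = mean(rows$error_bpm),
               sd_error = stats::sd(rows$error_bpm),
               mean_pct_error = mean(rows$pct_error),
               sd_pct_error = stats::sd(rows$pct_error),
               n_epochs = nrow(rows))
  }
  parts <- lapply(split(table, table$label), function(rows)
    one(rows$label[1], rows))
  out <- do.call(rbind, c(parts, list(one("whole record", table))))
  rownames(out) <- NULL
  out$method <- table$method[1]
  out
}

rem_boundaries <- function(hypno) {
  is_rem <- hypno$label == "REM"
  d <- diff(c(FALSE, is_rem, FALSE))
  epoch_s <- attr(hypno, "epoch_s")
  list(onset = hypno$epoch_start_s[which(d == 1)],
       offset = hypno$epoch_start_s[1] + epoch_s * (which(d == -1) - 1))
}

moving_average <- function(x, k) {
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
}

#' Whole-record report figure and tables
#'
#' Four aligned panels sharing the time axis: (A) 2-s moving-average heart
#' rate; (B) gold-standard versus extracted breathing rate; (C) hypnogram
#' with REM onsets (solid) and offsets (dotted) marked in every panel;
#' (D) per-epoch percentage error with a dashed reference line at 5 %.
#'
#' @param hr an [hr_series()].
#' @param br_edr,br_pressure the two [br_series()].
#' @param hypno a [hypnogram()].
#' @param errors a [epoch_errors()] table.
#' @param file image file (`.png`); `NULL` draws on the current device.
#' @param csv_dir if non-`NULL`, the underlying series and tables are also
#'   written there as CSV.
#' @return invisibly, the paths written.
#' @export
whole_record_report <- function(hr, br_edr, br_pressure, hypno, errors,
                                file = NULL, csv_dir = NULL) {
  paths <- character(0)
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 900)
    on.exit(grDevices::dev.off(), add = TRUE)
    paths <- c(paths, file)
  }
  op <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4.5, 1.5, 1),
                      oma = c(2, 0, 1, 0))
  on.exit(graphics::par(op), add = TRUE)
  xlim <- range(hr$times_s)
  k_hr <- max(1L, round(2 * hr$grid_rate_hz))
  rem <- rem_boundaries(hypno)
  add_rem <- function() {
    graphics::abline(v = rem$onset, lty = 1, col = "black")
    graphics::abline(v = rem$offset, lty = 3, col = "black")
  }

  graphics::plot(hr$times_s, moving_average(hr$hr_bpm, k_hr), type = "l",
                 xlim = xlim, xlab = "", ylab = "HR (bpm)",
                 main = "Heart rate (2-s moving average)", col = "grey25")
  add_rem()

  k_br <- max(1L, round(2 * br_edr$grid_rate_hz))
  graphics::plot(br_pressure$times_s, moving_average(br_pressure$br_bpm, k_br),
                 type = "l", col = "cyan3", xlim = xlim, xlab = "",
                 ylab = "BR (bpm)", main = "Breathing rate")
  graphics::lines(br_edr$times_s, moving_average(br_edr$br_bpm, k_br),
                  col = "red")
  graphics::legend("topright", c("pressure", br_edr$source), bty = "n",
                   col = c("cyan3", "red"), lty = 1)
  add_rem()

  lev <- c("N3", "N2", "N1", "REM0", "REM", "ECW", "W")
  yv <- match(hypno$label, lev)
  graphics::plot(hypno$epoch_start_s, yv, type = "s", yaxt = "n",
                 xlim = xlim, xlab = "", ylab = "stage",
                 main = "Hypnogram", col = "grey25")
  graphics::axis(2, at = seq_along(lev), labels = lev, las = 1, cex.axis = 0.8)
  add_rem()

  epoch_s <- attr(hypno, "epoch_s")
  graphics::plot(hypno$epoch_start_s[errors$epoch_index] + epoch_s / 2,
                 errors$pct_error, type = "h", xlim = xlim,
                 xlab = "time (s)", ylab = "%error",
                 main = sprintf("%s vs pressure, per-epoch %%error",
                                errors$method[1]), col = "grey25")
  graphics::abline(h = 5, lty = 2)
  add_rem()

  if (!is.null(csv_dir)) {
    dir.create(csv_dir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(csv_dir, "hr.csv")
    utils::write.csv(data.frame(time_s = hr$times_s, hr_bpm = hr$hr_bpm),
                     p1, row.names = FALSE)
    p2 <- file.path(csv_dir, "br.csv")
    utils::write.csv(data.frame(time_s = br_edr$times_s,
                                br_edr_bpm = br_edr$br_bpm,
                                br_pressure_bpm = br_pressure$br_bpm,
                                confidence = br_edr$confidence),
                     p2, row.names = FALSE)
    p3 <- file.path(csv_dir, "epoch_errors.csv")
    utils::write.csv(as.data.frame(errors), p3, row.names = FALSE)
    paths <- c(paths, p1, p2, p3)
  }
  invisible(paths)
}
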