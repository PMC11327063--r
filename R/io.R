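# --- minimal EDF (European Data Format, 16-bit continuous) -----------------
# Just enough of the format for PSG channel exchange: ASCII fixed-width
# header, one 16-bit little-endian data record stream, no annotations.

pad <- function(x, n) {
  x <- substr(as.character(x), 1, n)
  formatC(x, width = -n, flag = "-")
}

#' Write signals to an EDF file
#'
#' @param file output path.
#' @param signals list of channels, each a list with `label`, `samples`,
#'   `sample_rate_hz` and optionally `physical_dim`. Sampling rates times
#'   `record_duration_s` must be whole numbers.
#' @param record_duration_s EDF data-record length, seconds.
#' @param start optional `POSIXct` recording start.
#' @return the file path, invisibly.
#' @export
write_edf <- function(file, signals, record_duration_s = 1,
                      start = as.POSIXct("2000-01-01 00:00:00", tz = "UTC")) {
  ns <- length(signals)
  spr <- vapply(signals, function(s) s$sample_rate_hz * record_duration_s,
                numeric(1))
  if (any(abs(spr - round(spr)) > 1e-9))
    stop("sample_rate_hz * record_duration_s must be an integer for EDF")
  spr <- as.integer(round(spr))
  n_rec <- max(ceiling(vapply(signals, function(s) length(s$samples),
                              numeric(1)) / spr))

  con <- file(file, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeBin(charToRaw(pad(x, n)), con)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate X X X X", 80)
  wr(format(start, "%d.%m.%y"), 8)
  wr(format(start, "%H.%M.%S"), 8)
  wr(256 * (1 + ns), 8)
  wr("EDF", 44)
  wr(n_rec, 8)
  wr(format(record_duration_s), 8)
  wr(ns, 4)

  pmin_ <- numeric(ns); pmax_ <- numeric(ns)
  for (i in seq_len(ns)) {
    r <- range(signals[[i]]$samples, finite = TRUE)
    if (diff(r) == 0) r <- r + c(-1, 1)
    pmin_[i] <- r[1]; pmax_[i] <- r[2]
  }
  for (i in seq_len(ns)) wr(signals[[i]]$label, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(if (is.null(signals[[i]]$physical_dim)) ""
                            else signals[[i]]$physical_dim, 8)
  for (i in seq_len(ns)) wr(format(pmin_[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(format(pmax_[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(-32768L, 8)
  for (i in seq_len(ns)) wr(32767L, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(spr[i], 8)
  for (i in seq_len(ns)) wr("", 32)

  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- signals[[i]]$samples
    x <- c(x, rep(x[length(x)], n_rec * spr[i] - length(x)))
    d <- round((x - pmin_[i]) / (pmax_[i] - pmin_[i]) * 65535 - 32768)
    dig[[i]] <- as.integer(pmin(32767, pmax(-32768, d)))
  }
  for (r in seq_len(n_rec))
    for (i in seq_len(ns))
      writeBin(dig[[i]][((r - 1) * spr[i] + 1):(r * spr[i])], con,
               size = 2, endian = "little")
  invisible(file)
}

#' Read signals from an EDF file
#'
#' @param file EDF path.
#' @param labels channel labels to read (`NULL` for all).
#' @return list of channels (`label`, `samples` in physical units,
#'   `sample_rate_hz`), with the header in attribute `header`.
#' @export
read_edf <- function(file, labels = NULL) {
  con <- file(file, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  date <- rd(8); time <- rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  lab <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  dim_ <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  raw_sig <- lapply(seq_len(ns), function(i) integer(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", spr[i], size = 2, signed = TRUE,
                   endian = "little")
      raw_sig[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- v
    }
  }
  out <- lapply(seq_len(ns), function(i) {
    scale <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    list(label = lab[i],
         samples = (raw_sig[[i]] - dmin_[i]) * scale + pmin_[i],
         sample_rate_hz = spr[i] / rec_dur,
         physical_dim = dim_[i])
  })
  names(out) <- lab
  if (!is.null(labels)) {
    miss <- setdiff(labels, lab)
    if (length(miss))
      stop("channel(s) not in EDF: ", paste(miss, collapse = ", "))
    out <- out[labels]
  }
  attr(out, "header") <- list(version = version, patient = patient,
                              recording = recording, date = date,
                              time = time, n_records = n_rec,
                              record_duration_s = rec_dur)
  out
}

# --- hypnograms, event times, series ---------------------------------------

#' Read and write hypnograms
#'
#' Plain-text format: a header line `epoch_s=<n>` followed by one stage
#' label per line. CSV format: columns `epoch_start_s,label`.
#'
#' @param hypno a [hypnogram()].
#' @param file path.
#' @param format `"text"` or `"csv"`.
#' @return `read_hypnogram()` returns a [hypnogram()];
#'   `write_hypnogram()` returns the path invisibly.
#' @export
write_hypnogram <- function(hypno, file, format = c("text", "csv")) {
  format <- match.arg(format)
  if (format == "text") {
    writeLines(c(sprintf("epoch_s=%g", attr(hypno, "epoch_s")), hypno$label),
               file)
  } else {
    utils::write.csv(data.frame(epoch_start_s = hypno$epoch_start_s,
                                label = hypno$label),
                     file, row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(file, format = c("text", "csv")) {
  format <- match.arg(format)
  if (format == "text") {
    ln <- readLines(file)
    if (!grepl("^epoch_s=", ln[1]))
      stop("hypnogram text file must start with an 'epoch_s=' header")
    epoch_s <- as.numeric(sub("^epoch_s=", "", ln[1]))
    hypnogram(ln[-1][nzchar(ln[-1])], epoch_s = epoch_s)
  } else {
    d <- utils::read.csv(file, stringsAsFactors = FALSE)
    epoch_s <- if (nrow(d) > 1) d$epoch_start_s[2] - d$epoch_start_s[1] else 30
    hypnogram(d$label, epoch_s = epoch_s, start_s = d$epoch_start_s[1])
  }
}

#' Read and write event-time files (one time in seconds per line)
#' @param times_s numeric vector of event times.
#' @param file path.
#' @return `read_event_times()` returns a numeric vector.
#' @export
write_event_times <- function(times_s, file) {
  writeLines(format(times_s, digits = 12, trim = TRUE, scientific = FALSE),
             file)
  invisible(file)
}

#' @rdname write_event_times
#' @export
read_event_times <- function(file) {
  x <- as.numeric(readLines(file))
  if (anyNA(x)) stop("non-numeric line in event-time file")
  x
}

#' Write a breathing- or heart-rate series as CSV
#' @param x a [br_series()] or [hr_series()].
#' @param file path.
#' @return the path, invisibly.
#' @export
write_series_csv <- function(x, file) {
  d <- if (inherits(x, "br_series")) {
    data.frame(time_s = x$times_s, br_bpm = x$br_bpm, source = x$source,
               confidence = x$confidence)
  } else {
    data.frame(time_s = x$times_s, hr_bpm = x$hr_bpm)
  }
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' Read a breathing- or heart-rate series from CSV
#' @param file path written by [write_series_csv()].
#' @return a [br_series()] or [hr_series()] according to the columns found.
#' @export
read_series_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  rate <- 1 / stats::median(diff(d$time_s))
  if ("br_bpm" %in% names(d)) {
    br_series(d$br_bpm, d$time_s, rate, source = d$source[1],
              confidence = d$confidence)
  } else {
    hr_series(d$hr_bpm, d$time_s, rate)
  }
}

# --- scenario / config files ------------------------------------------------

#' Read a simulation scenario from a YAML file
#'
#' Keys mirror the arguments of [sim_scenario()]; `br_trajectory` may be a
#' number or a list of `{time_s, br_bpm}` knots; `interferers` a list of
#' `{start_s, stop_s, freq_hz, amplitude_bpm}`; `apnea_windows` a list of
#' `{start_s, stop_s}`.
#'
#' @param file YAML path.
#' @return a [sim_scenario()].
#' @export
read_scenario_yaml <- function(file) {
  y <- yaml::read_yaml(file)
  if (!is.null(y$br_trajectory) && is.list(y$br_trajectory))
    y$br_trajectory <- do.call(rbind, lapply(y$br_trajectory, function(k)
      data.frame(time_s = k$time_s, br_bpm = k$br_bpm)))
  if (!is.null(y$interferers))
    y$interferers <- do.call(rbind, lapply(y$interferers, as.data.frame))
  if (!is.null(y$apnea_windows))
    y$apnea_windows <- do.call(rbind, lapply(y$apnea_windows, function(k)
      data.frame(start_s = k$start_s, stop_s = k$stop_s)))
  do.call(sim_scenario, y)
}

#' Read a pipeline configuration from a YAML file
#' @param file YAML path with any subset of the [scedr_config()] keys.
#' @return a [scedr_config()].
#' @export
read_config_yaml <- function(file) {
  do.call(scedr_config, yaml::read_yaml(file))
}
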