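#' Waveform time integration over 60-s intervals
#'
#' Reduces a waveform to the 1-min grid: the value for minute `m` is the
#' trapezoidal time integral of the waveform over `[m, m+1)` minutes divided
#' by the integrated span.  A minute whose fraction of invalid (`NA`) samples
#' exceeds `invalid_frac` is flagged missing; otherwise invalid samples are
#' dropped from the integration.  Only complete minutes are emitted.
#'
#' @param signal a [WaveformSignal-class].
#' @param invalid_frac maximum tolerated fraction of invalid samples per
#'   minute (default 0.25).
#' @return A [MinuteSeries-class].
#' @export
integrate60s <- function(signal, invalid_frac = 0.25) {
  stopifnot(is(signal, "WaveformSignal"))
  y <- signal@samples
  if (length(y) == 0L) stop("empty signal")
  fs <- signal@fs
  spm <- fs * 60
  if (spm < 1) stop("fewer than one sample per 60-s window")
  n_min <- floor(length(y) / spm)
  if (n_min < 1L) stop("signal shorter than one minute")
  vals <- rep(NA_real_, n_min)
  miss <- rep(TRUE, n_min)
  t <- (seq_along(y) - 1) / fs
  for (m in seq_len(n_min)) {
    lo <- floor((m - 1) * spm) + 1L
    hi <- min(length(y), floor(m * spm) + 1L)  # shared edge sample
    ys <- y[lo:hi]; ts <- t[lo:hi]
    bad <- is.na(ys)
    if (mean(bad[-length(bad)]) > invalid_frac) next
    ys <- ys[!bad]; ts <- ts[!bad]
    if (length(ys) < 2L) next
    vals[m] <- pracma::trapz(ts, ys) / (ts[length(ts)] - ts[1])
    miss[m] <- FALSE
  }
  minuteSeries(vals, start_min = round(signal@t0 / 60), missing_mask = miss)
}

#' Align minute series onto the first-72-h grid
#'
#' Trims and pads (with missing) a set of minute series, each carrying its
#' own `start_min` relative to monitoring onset, onto a common
#' `[0, total_min)` grid.
#'
#' @param series named list of [MinuteSeries-class] objects on the same
#'   clock.
#' @param patient_id patient identifier for the resulting panel.
#' @param total_min grid length in minutes (default 4320 = 72 h).
#' @return A [MinutePanel-class].
#' @export
cropAlign <- function(series, patient_id = "p1", total_min = 4320) {
  stopifnot(length(series) >= 1L, !is.null(names(series)))
  no_overlap <- character()
  out <- vector("list", length(series)); names(out) <- names(series)
  for (nm in names(series)) {
    s <- series[[nm]]
    pos <- s@start_min + seq_along(s@values) - 1   # absolute minutes
    keep <- pos >= 0 & pos < total_min
    if (!any(keep)) { no_overlap <- c(no_overlap, nm); next }
    vals <- rep(NA_real_, total_min); miss <- rep(TRUE, total_min)
    vals[pos[keep] + 1] <- s@values[keep]
    miss[pos[keep] + 1] <- s@missing_mask[keep]
    out[[nm]] <- minuteSeries(vals, start_min = 0, missing_mask = miss)
  }
  if (length(no_overlap))
    stop(sprintf("series with no overlap with the %d-min grid: %s",
                 total_min, paste(no_overlap, collapse = ", ")))
  minutePanel(out, patient_id = patient_id)
}

#' Read and write waveform CSV files
#'
#' The CSV layout is two columns, `time_s` and `value`, written at full
#' precision; the sampling rate is recovered from the time column on read.
#'
#' @param signal a [WaveformSignal-class].
#' @param path file path.
#' @export
writeWaveformCSV <- function(signal, path) {
  stopifnot(is(signal, "WaveformSignal"))
  t <- signal@t0 + (seq_along(signal@samples) - 1) / signal@fs
  data.table::fwrite(data.table::data.table(time_s = t,
                                            value = signal@samples),
                     path)
  invisible(path)
}

#' @rdname writeWaveformCSV
#' @param label channel label to attach (`"ABP"` or `"ICP"`).
#' @return `readWaveformCSV()` returns a [WaveformSignal-class].
#' @export
readWaveformCSV <- function(path, label = "ABP") {
  dt <- data.table::fread(path)
  for (col in c("time_s", "value"))
    if (!col %in% names(dt))
      stop(sprintf("waveform CSV lacks required column '%s'", col))
  dts <- diff(dt$time_s)
  if (length(dts) == 0L) stop("waveform CSV contains a single sample")
  fs <- 1 / median(dts)
  waveformSignal(dt$value, fs = fs, t0 = dt$time_s[1], label = label)
}

#' Read and write minute-panel CSV files
#'
#' Layout: columns `time_min`, `icp`, `cpp`, `prx`, `brs`, `lfhf`; missing
#' minutes are empty cells.
#'
#' @param panel a [MinutePanel-class].
#' @param path file path.
#' @export
writePanelCSV <- function(panel, path) {
  stopifnot(is(panel, "MinutePanel"))
  start <- panel@series[[1]]@start_min
  dt <- data.table::data.table(
    time_min = start + seq_len(panel@length_min) - 1)
  for (nm in PANEL_INDICES)
    dt[[nm]] <- if (nm %in% names(panel@series))
      seriesValues(panel@series[[nm]]) else NA_real_
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname writePanelCSV
#' @param patient_id patient identifier for the panel.
#' @return `readPanelCSV()` returns a [MinutePanel-class].
#' @export
readPanelCSV <- function(path, patient_id = "p1") {
  dt <- data.table::fread(path)
  for (col in c("time_min", PANEL_INDICES))
    if (!col %in% names(dt))
      stop(sprintf("panel CSV lacks required column '%s'", col))
  series <- lapply(PANEL_INDICES, function(nm)
    minuteSeries(dt[[nm]], start_min = dt$time_min[1]))
  names(series) <- PANEL_INDICES
  minutePanel(series, patient_id = patient_id)
}

#' Read and write patient metadata CSV files
#'
#' Layout: `patient_id, age, gcs, pupils, extracranial, outcome_short,
#' outcome_long`.
#'
#' @param records data.frame of patient records.
#' @param path file path.
#' @export
writeMetadataCSV <- function(records, path) {
  data.table::fwrite(data.table::as.data.table(records), path)
  invisible(path)
}

#' @rdname writeMetadataCSV
#' @return `readMetadataCSV()` returns a data.frame.
#' @export
readMetadataCSV <- function(path) {
  dt <- data.table::fread(path)
  req <- c("patient_id", "age", "gcs", "pupils", "extracranial",
           "outcome_short", "outcome_long")
  for (col in req)
    if (!col %in% names(dt))
      stop(sprintf("metadata CSV lacks required column '%s'", col))
  as.data.frame(dt)
}
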