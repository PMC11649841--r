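#' @import methods
#' @importFrom stats median quantile sd cor complete.cases rnorm runif approx
#'   fisher.test chisq.test wilcox.test shapiro.test pt setNames fft predict
#' @importFrom utils head tail
NULL

#' Uniformly sampled pressure waveform
#'
#' Container for a single-channel pressure waveform (arterial or intracranial),
#' sampled uniformly at `fs` Hz starting at `t0` seconds.  Invalid samples are
#' represented as `NA` rather than sentinel values so that downstream
#' aggregation can count them exactly.
#'
#' @slot samples numeric vector, pressure in mmHg (`NA` = invalid sample).
#' @slot fs sampling frequency in Hz.
#' @slot t0 start time in seconds from monitoring onset.
#' @slot label channel label, `"ABP"` or `"ICP"`.
#'
#' @export
setClass("WaveformSignal",
  representation(samples = "numeric", fs = "numeric", t0 = "numeric",
                 label = "character"),
  prototype(samples = numeric(), fs = 100, t0 = 0, label = "ABP"))

setValidity("WaveformSignal", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@samples) < 1L)
    msg <- c(msg, "waveform must contain at least one sample")
  if (!object@label %in% c("ABP", "ICP"))
    msg <- c(msg, "label must be 'ABP' or 'ICP'")
  if (length(msg)) msg else TRUE
})

#' One-minute-resolution index series
#'
#' A derived neuromonitoring index on the 1-minute grid, with an explicit
#' missingness mask.  Minute bins are half-open `[m, m+1)` minutes from
#' monitoring onset, 0-based.
#'
#' @slot values numeric vector (units depend on the index); must be finite
#'   wherever `missing_mask` is `FALSE`.
#' @slot start_min first minute bin covered by the series.
#' @slot missing_mask logical vector, `TRUE` where the minute is missing.
#'
#' @export
setClass("MinuteSeries",
  representation(values = "numeric", start_min = "numeric",
                 missing_mask = "logical"),
  prototype(values = numeric(), start_min = 0, missing_mask = logical()))

setValidity("MinuteSeries", function(object) {
  msg <- character()
  if (length(object@values) != length(object@missing_mask))
    msg <- c(msg, "values and missing_mask lengths differ")
  if (length(object@start_min) != 1L || object@start_min %% 1 != 0)
    msg <- c(msg, "start_min must be a single integer-valued number")
  bad <- !object@missing_mask & !is.finite(object@values)
  if (any(bad))
    msg <- c(msg, "non-missing values must be finite")
  if (length(msg)) msg else TRUE
})

#' Aligned panel of minute-resolution indices
#'
#' Holds the five derived indices (`icp`, `cpp`, `prx`, `brs`, `lfhf`) for one
#' patient on a shared minute grid covering at most the first 72 h (4320 min)
#' of monitoring.
#'
#' @slot patient_id character scalar.
#' @slot series named list of [MinuteSeries-class] objects sharing start and
#'   length; names from `icp`, `cpp`, `prx`, `brs`, `lfhf`.
#' @slot length_min common series length in minutes.
#'
#' @export
setClass("MinutePanel",
  representation(patient_id = "character", series = "list",
                 length_min = "numeric"))

PANEL_INDICES <- c("icp", "cpp", "prx", "brs", "lfhf")

setValidity("MinutePanel", function(object) {
  msg <- character()
  if (!all(names(object@series) %in% PANEL_INDICES))
    msg <- c(msg, sprintf("series names must be among: %s",
                          paste(PANEL_INDICES, collapse = ", ")))
  lens <- vapply(object@series, function(s) length(s@values), numeric(1))
  starts <- vapply(object@series, function(s) s@start_min, numeric(1))
  if (length(lens) && (length(unique(lens)) != 1L ||
                       length(unique(starts)) != 1L))
    msg <- c(msg, "all member series must share start and length")
  if (length(lens) && lens[1] != object@length_min)
    msg <- c(msg, "length_min disagrees with member series")
  if (object@length_min > 4320)
    msg <- c(msg, "panel longer than 72 h (4320 min)")
  if (length(msg)) msg else TRUE
})

#' Windowed time-lagged cross-correlation matrix
#'
#' A `K x J` matrix of Pearson correlations between two minute-resolution
#' series: row `k` is the `k`-th sub-window of the `N`-minute analysis window,
#' column `j` the lag `j - J/2` minutes applied to the second series.  Entries
#' are in `[-1, 1]`; entries that could not be computed (insufficient valid
#' pairs, zero variance) are `NA`.
#'
#' @slot values numeric `K x J` matrix.
#' @slot patient_id character scalar.
#' @slot window_start analysis-window start, minutes from onset.
#' @slot params the [wtlccParams()] list used to build the matrix.
#' @slot pair character vector of length 2: names of (I1, I2).
#'
#' @export
setClass("WTLCCMatrix",
  representation(values = "matrix", patient_id = "character",
                 window_start = "numeric", params = "list",
                 pair = "character"))

setValidity("WTLCCMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (any(is.finite(v) & (v < -1 - 1e-12 | v > 1 + 1e-12)))
    msg <- c(msg, "correlation entries must lie in [-1, 1]")
  if (length(object@pair) != 2L)
    msg <- c(msg, "pair must name exactly two series")
  p <- object@params
  if (!is.null(p$K) && nrow(v) != p$K)
    msg <- c(msg, "row count disagrees with params$K")
  if (!is.null(p$J) && ncol(v) != p$J)
    msg <- c(msg, "column count disagrees with params$J")
  if (length(msg)) msg else TRUE
})

#' Fitted convolutional outcome scorer
#'
#' Opaque fitted CNN mapping WTLCC matrices to outcome scores in `[0, 1]`
#' (probability of unfavourable outcome).  Exposes per-matrix scoring,
#' patient-level aggregation and penultimate-layer embeddings through
#' [scoreMatrices()], [scorePatient()] and [embedPatient()].
#'
#' @slot weights list of fitted weight arrays (internal layout).
#' @slot config the [cnnConfig()] used for training.
#' @slot input_shape integer vector `(K, J)` accepted by the network.
#' @slot embedding_dim length of the penultimate-layer embedding.
#' @slot history data.frame of per-epoch training/validation loss.
#'
#' @export
setClass("TrainedScorer",
  representation(weights = "list", config = "list",
                 input_shape = "numeric", embedding_dim = "numeric",
                 history = "data.frame"))

setMethod("show", "WaveformSignal", function(object) {
  dur <- length(object@samples) / object@fs
  cat(sprintf("WaveformSignal '%s': %d samples @ %g Hz (%.1f s), %d invalid\n",
              object@label, length(object@samples), object@fs, dur,
              sum(is.na(object@samples))))
})

setMethod("show", "MinuteSeries", function(object) {
  cat(sprintf("MinuteSeries: %d min from minute %d, %d missing\n",
              length(object@values), as.integer(object@start_min),
              sum(object@missing_mask)))
})

setMethod("show", "MinutePanel", function(object) {
  cat(sprintf("MinutePanel '%s': %d min, indices: %s\n", object@patient_id,
              as.integer(object@length_min),
              paste(names(object@series), collapse = ", ")))
})

setMethod("show", "WTLCCMatrix", function(object) {
  cat(sprintf("WTLCCMatrix %s~%s [%dx%d] patient '%s' start %d min\n",
              object@pair[1], object@pair[2], nrow(object@values),
              ncol(object@values), object@patient_id,
              as.integer(object@window_start)))
})

setMethod("show", "TrainedScorer", function(object) {
  cat(sprintf(
    "TrainedScorer: input %dx%d, embedding dim %d, %d conv block(s)\n",
    object@input_shape[1], object@input_shape[2], object@embedding_dim,
    length(object@config$conv_blocks)))
})

# ---- constructors & accessors -------------------------------------------

#' Construct a WaveformSignal
#'
#' @param samples numeric vector of pressures (mmHg); `NA` marks invalid
#'   samples.
#' @param fs sampling frequency, Hz.
#' @param t0 start time in seconds (default 0).
#' @param label `"ABP"` or `"ICP"`.
#' @return A [WaveformSignal-class] object.
#' @export
waveformSignal <- function(samples, fs, t0 = 0, label = "ABP") {
  new("WaveformSignal", samples = as.numeric(samples), fs = fs, t0 = t0,
      label = label)
}

#' Construct a MinuteSeries
#'
#' @param values numeric vector of minute values.
#' @param start_min first minute bin (default 0).
#' @param missing_mask logical mask; defaults to `is.na(values)`.
#' @return A [MinuteSeries-class] object.
#' @export
minuteSeries <- function(values, start_min = 0, missing_mask = is.na(values)) {
  values[missing_mask] <- NA_real_
  new("MinuteSeries", values = as.numeric(values), start_min = start_min,
      missing_mask = missing_mask)
}

#' Construct a MinutePanel from minute series
#'
#' @param series named list of [MinuteSeries-class] objects (names among
#'   `icp`, `cpp`, `prx`, `brs`, `lfhf`).
#' @param patient_id character scalar.
#' @return A [MinutePanel-class] object.
#' @export
minutePanel <- function(series, patient_id = "p1") {
  len <- if (length(series)) length(series[[1]]@values) else 0
  new("MinutePanel", patient_id = patient_id, series = series,
      length_min = len)
}

#' @rdname minutePanel
#' @param x a `MinutePanel`.
#' @param name index name (e.g. `"icp"`).
#' @return `panelSeries()` returns the named [MinuteSeries-class].
#' @export
panelSeries <- function(x, name) {
  stopifnot(is(x, "MinutePanel"))
  if (!name %in% names(x@series))
    stop(sprintf("panel has no series '%s'", name))
  x@series[[name]]
}

#' Minute values with missing entries as NA
#'
#' @param x a [MinuteSeries-class].
#' @return numeric vector with `NA` at missing minutes.
#' @export
seriesValues <- function(x) {
  v <- x@values
  v[x@missing_mask] <- NA_real_
  v
}

#' @rdname seriesValues
#' @export
seriesMissing <- function(x) x@missing_mask

#' Matrix values of a WTLCC matrix
#'
#' @param x a [WTLCCMatrix-class].
#' @return numeric `K x J` matrix (missing entries `NA`).
#' @export
matrixValues <- function(x) x@values

#' @rdname matrixValues
#' @export
matrixPair <- function(x) x@pair

#' @rdname matrixValues
#' @export
matrixPatient <- function(x) x@patient_id

#' @rdname matrixValues
#' @export
matrixWindowStart <- function(x) x@window_start
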