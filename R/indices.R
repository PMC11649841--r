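#' Beat-by-beat series from an arterial waveform
#'
#' Systolic peak times, per-beat systolic pressure and interbeat interval
#' (interval between consecutive systolic peaks).
#'
#' @slot peak_times seconds, strictly increasing.
#' @slot sbp systolic pressure per beat, mmHg.
#' @slot ibi_ms interbeat interval ending at each beat, ms (`NA` for the
#'   first beat); out-of-band intervals (outside 250-2000 ms) are flagged.
#' @slot valid logical per beat.
#'
#' @export
setClass("BeatSeries",
  representation(peak_times = "numeric", sbp = "numeric", ibi_ms = "numeric",
                 valid = "logical"))

setValidity("BeatSeries", function(object) {
  if (length(object@peak_times) >= 2 && any(diff(object@peak_times) <= 0))
    return("peak_times must be strictly increasing")
  TRUE
})

setMethod("show", "BeatSeries", function(object) {
  cat(sprintf("BeatSeries: %d beats over %.1f s, %d flagged invalid\n",
              length(object@peak_times),
              diff(range(object@peak_times)), sum(!object@valid)))
})

#' Construct a BeatSeries from peak times and systolic pressures
#'
#' @param peak_times seconds, strictly increasing.
#' @param sbp systolic pressure per beat, mmHg.
#' @param ibi_band plausibility band for interbeat intervals, ms.
#' @return A [BeatSeries-class].
#' @export
beatSeries <- function(peak_times, sbp, ibi_band = c(250, 2000)) {
  ibi <- c(NA_real_, diff(peak_times) * 1000)
  valid <- is.na(ibi) | (ibi >= ibi_band[1] & ibi <= ibi_band[2])
  new("BeatSeries", peak_times = peak_times, sbp = sbp, ibi_ms = ibi,
      valid = valid)
}

#' Detect systolic peaks in an arterial pressure waveform
#'
#' One peak per cardiac cycle: local maxima exceeding an adaptive (10-s
#' block) threshold, separated by a 250-ms refractory period.  Peak time and
#' height are refined by parabolic interpolation through the three samples
#' around each maximum.  Flat-line blocks yield no beats.
#'
#' @param abp a [WaveformSignal-class] (fs >= 50 Hz).
#' @return A [BeatSeries-class].
#' @export
detectSystolicPeaks <- function(abp) {
  stopifnot(is(abp, "WaveformSignal"))
  if (abp@fs < 50) stop("fs must be >= 50 Hz for beat detection")
  y <- abp@samples
  fs <- abp@fs
  pk <- pracma::findpeaks(y, minpeakdistance = max(1L, round(0.25 * fs)),
                          zero = "0")
  if (is.null(pk) || nrow(pk) < 2) stop("<2 peaks detected")
  idx <- sort(pk[, 2])
  # adaptive threshold: within each 10-s block keep peaks above the midpoint
  # of the block's range; flat blocks (range < 1 mmHg) contribute no beats
  blk <- floor((idx - 1) / (10 * fs))
  keep <- logical(length(idx))
  for (b in unique(blk)) {
    sel <- blk == b
    lo <- b * 10 * fs + 1; hi <- min(length(y), (b + 1) * 10 * fs)
    seg <- y[lo:hi]
    rng <- diff(range(seg, na.rm = TRUE))
    if (!is.finite(rng) || rng < 1) next
    thr <- mean(range(seg, na.rm = TRUE))
    keep[sel] <- !is.na(y[idx[sel]]) & y[idx[sel]] > thr
  }
  idx <- idx[keep]
  if (length(idx) < 2) stop("<2 peaks detected")
  # parabolic refinement
  t_pk <- numeric(length(idx)); h_pk <- numeric(length(idx))
  for (i in seq_along(idx)) {
    p <- idx[i]
    if (p > 1 && p < length(y) &&
        !anyNA(y[(p - 1):(p + 1)])) {
      a <- y[p - 1]; b <- y[p]; c <- y[p + 1]
      den <- a - 2 * b + c
      dd <- if (abs(den) > 1e-12) 0.5 * (a - c) / den else 0
      dd <- max(-0.5, min(0.5, dd))
      t_pk[i] <- (p - 1 + dd) / fs
      h_pk[i] <- b - 0.25 * (a - c) * dd
    } else {
      t_pk[i] <- (p - 1) / fs
      h_pk[i] <- y[p]
    }
  }
  beatSeries(t_pk, h_pk)
}

#' Cerebral perfusion pressure from aligned minute series
#'
#' `CPP[m] = ABP[m] - ICP[m]`; missing wherever either input is missing.
#'
#' @param abp_min,icp_min aligned [MinuteSeries-class] objects (mean ABP and
#'   mean ICP, mmHg).
#' @return A [MinuteSeries-class].
#' @export
computeCPP <- function(abp_min, icp_min) {
  stopifnot(is(abp_min, "MinuteSeries"), is(icp_min, "MinuteSeries"))
  if (length(abp_min@values) != length(icp_min@values))
    stop("ABP and ICP minute series lengths differ")
  v <- seriesValues(abp_min) - seriesValues(icp_min)
  minuteSeries(v, start_min = abp_min@start_min)
}

#' 10-s means of a waveform
#'
#' @param signal a [WaveformSignal-class].
#' @param invalid_frac maximum tolerated fraction of invalid samples per bin.
#' @return list with `values` (mmHg per 10-s bin), `start_s`, `missing_mask`.
#' @export
tenSecondMeans <- function(signal, invalid_frac = 0.25) {
  y <- signal@samples
  spb <- signal@fs * 10
  n_bin <- floor(length(y) / spb)
  if (n_bin < 1) stop("signal shorter than 10 s")
  vals <- rep(NA_real_, n_bin); miss <- rep(TRUE, n_bin)
  for (b in seq_len(n_bin)) {
    seg <- y[(floor((b - 1) * spb) + 1):floor(b * spb)]
    if (mean(is.na(seg)) > invalid_frac) next
    vals[b] <- mean(seg, na.rm = TRUE); miss[b] <- FALSE
  }
  list(values = vals, start_s = signal@t0, missing_mask = miss)
}

#' Pressure reactivity index (PRx)
#'
#' Pearson correlation between slow waves of ABP and ICP: both waveforms are
#' averaged over 10-s intervals, the correlation is computed over a 5-min
#' moving window (30 pairs) updated every 10 s, and the six updates within
#' each minute are averaged into the minute value.  A window with more than
#' half of its pairs missing, or with zero variance in either channel, yields
#' a missing (not zero) correlation.
#'
#' @param abp,icp [WaveformSignal-class] objects covering >= 5 min.
#' @return A [MinuteSeries-class] of minute PRx values in `[-1, 1]`.
#' @export
computePRx <- function(abp, icp) {
  a10 <- tenSecondMeans(abp); i10 <- tenSecondMeans(icp)
  n_bin <- min(length(a10$values), length(i10$values))
  if (n_bin < 30) stop("need at least 5 min of overlapping signal")
  r <- prxWindows(a10$values[seq_len(n_bin)], i10$values[seq_len(n_bin)])
  n_min <- floor(n_bin / 6)
  vals <- rep(NA_real_, n_min)
  for (m in seq_len(n_min)) {
    win <- r[(6 * (m - 1) + 1):(6 * m)]
    if (any(!is.na(win))) vals[m] <- mean(win, na.rm = TRUE)
  }
  minuteSeries(vals, start_min = round(abp@t0 / 60))
}

# 5-min (30-pair) moving Pearson correlation updated every 10-s bin; element
# i uses bins (i-29)..i and is NA for i < 30, for windows with > 50% missing
# pairs, and for zero-variance windows.
prxWindows <- function(a, b, width = 30L, max_missing = 0.5) {
  n <- length(a)
  r <- rep(NA_real_, n)
  for (i in seq(width, n)) {
    ia <- a[(i - width + 1L):i]; ib <- b[(i - width + 1L):i]
    ok <- !is.na(ia) & !is.na(ib)
    if (mean(!ok) > max_missing) next
    if (sum(ok) < 3) next
    va <- ia[ok]; vb <- ib[ok]
    if (sd(va) == 0 || sd(vb) == 0) next
    r[i] <- cor(va, vb)
  }
  r
}

#' Baroreflex sensitivity by sequential cross-correlation (xBRS)
#'
#' Beat-wise systolic pressure and interbeat interval are resampled to a 1-s
#' grid; for every 10-s segment the interval series is correlated against the
#' pressure series at candidate delays of 0-5 s.  The delay with the highest
#' positive correlation is taken; if that correlation is significant the
#' regression slope of interval on pressure (ms/mmHg) is recorded.  The
#' minute value is the mean of accepted segment slopes starting in that
#' minute; a minute with no accepted segment is missing.
#'
#' The significance rule is one-sided at `p_threshold` applied to the best
#' delay, with a Sidak-style correction for an effective number `m_eff` of
#' independent looks.  The naive per-segment t test is anticonservative
#' here for two reasons: the best of six candidate delays is selected, and
#' resampling beat-wise series to the 1-s grid induces serial correlation
#' that lowers the effective sample size.  The default `m_eff = 12` was
#' calibrated on the independence null (no baroreflex, pure interval noise)
#' so that the realized acceptance rate matches the nominal level.
#'
#' @param beats a [BeatSeries-class].
#' @param delays candidate delays, s.
#' @param p_threshold segment acceptance level (default 0.01).
#' @param m_eff effective number of independent looks used in the Sidak
#'   correction.
#' @return A [MinuteSeries-class] of BRS (ms/mmHg, >= 0) with attribute
#'   `acceptance_rate` (fraction of segments accepted).
#' @export
computeBRS <- function(beats, delays = 0:5, p_threshold = 0.01, m_eff = 12) {
  stopifnot(is(beats, "BeatSeries"))
  tp <- beats@peak_times
  if (diff(range(tp)) < 10) stop("need at least 10 s of beats")
  ok <- beats@valid & !is.na(beats@ibi_ms)
  tg <- seq(ceiling(tp[1]), floor(tp[length(tp)]))
  sbp_g <- approx(tp, beats@sbp, xout = tg, rule = 1)$y
  ibi_g <- approx(tp[ok], beats@ibi_ms[ok], xout = tg, rule = 1)$y
  T <- length(tg)
  seg_len <- 10L
  max_d <- max(delays)
  n_seg <- T - seg_len - max_d + 1L
  if (n_seg < 1) stop("need at least 10 s of beats")
  slope <- rep(NA_real_, n_seg)
  n_tested <- 0L; n_accept <- 0L
  for (st in seq_len(n_seg)) {
    xs <- sbp_g[st:(st + seg_len - 1L)]
    if (anyNA(xs) || sd(xs) < 1e-8) next
    best_r <- -Inf; best_d <- NA_integer_
    for (d in delays) {
      ys <- ibi_g[(st + d):(st + d + seg_len - 1L)]
      if (anyNA(ys) || sd(ys) == 0) next
      r <- cor(xs, ys)
      if (r > best_r) { best_r <- r; best_d <- d }
    }
    if (!is.finite(best_r) || best_r <= 0) next
    n_tested <- n_tested + 1L
    nn <- seg_len
    tt <- best_r * sqrt((nn - 2) / (1 - best_r^2))
    p1 <- pt(tt, df = nn - 2, lower.tail = FALSE)   # one-sided
    p_adj <- 1 - (1 - p1)^m_eff
    if (p_adj < p_threshold) {
      ys <- ibi_g[(st + best_d):(st + best_d + seg_len - 1L)]
      slope[st] <- best_r * sd(ys) / sd(xs)
      n_accept <- n_accept + 1L
    }
  }
  seg_start_s <- tg[seq_len(n_seg)]
  n_min <- floor((tg[T] + 1) / 60)
  vals <- rep(NA_real_, n_min)
  for (m in seq_len(n_min)) {
    sel <- seg_start_s >= (m - 1) * 60 & seg_start_s < m * 60
    sl <- slope[sel]
    if (any(!is.na(sl))) vals[m] <- mean(sl, na.rm = TRUE)
  }
  out <- minuteSeries(vals, start_min = 0)
  attr(out, "acceptance_rate") <- if (n_seg > 0) n_accept / n_seg else NA_real_
  attr(out, "n_segments") <- n_seg
  out
}

#' Lomb-Scargle periodogram for unevenly sampled series
#'
#' Classic form with the time-offset tau that makes the sine and cosine
#' basis orthogonal over the actual sample times.  On an evenly spaced grid
#' evaluated at Fourier frequencies it reduces to the classical periodogram
#' `|FFT|^2 / n`.
#'
#' @param t sample times, s.
#' @param y values (centred internally).
#' @param freq frequencies to evaluate, Hz.
#' @return numeric vector of spectral power (units of `y^2`).
#' @export
lombScargle <- function(t, y, freq) {
  y <- y - mean(y)
  vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  }, numeric(1))
}

#' LF/HF heart-rate-variability ratio
#'
#' Per right-aligned window, the Lomb-Scargle periodogram of the unevenly
#' sampled interbeat-interval series is integrated over the LF (0.04-0.15 Hz)
#' and HF (0.15-0.40 Hz) bands; the minute value is their ratio for the
#' window ending at that minute.  Windows with fewer than half the expected
#' beats, or with HF power below a numerical floor, are missing.
#'
#' @param beats a [BeatSeries-class].
#' @param window_min analysis window, min (default 5).
#' @param step_min step between windows, min (default 1).
#' @param lf_band,hf_band frequency bands, Hz.
#' @param hf_floor HF power floor below which the ratio is deemed unstable.
#' @return A [MinuteSeries-class] of LF/HF values (>= 0).
#' @export
computeLFHF <- function(beats, window_min = 5, step_min = 1,
                        lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40),
                        hf_floor = 1e-12) {
  stopifnot(is(beats, "BeatSeries"))
  if (window_min < 2) stop("window must be >= 2 min")
  tp <- beats@peak_times
  ok <- beats@valid & !is.na(beats@ibi_ms)
  tp <- tp[ok]; ibi <- beats@ibi_ms[ok]
  win_s <- window_min * 60
  total_min <- floor(tp[length(tp)] / 60)
  if (total_min < window_min) stop("signal shorter than one window")
  med_ibi_s <- median(diff(tp))
  expected <- win_s / med_ibi_s
  freq <- seq(0.02, 0.45, by = 1 / (4 * win_s))
  vals <- rep(NA_real_, total_min)
  for (m in seq(window_min, total_min, by = step_min)) {
    sel <- tp > (m - window_min) * 60 & tp <= m * 60
    if (sum(sel) < 0.5 * expected) next
    if (sum(sel) < 8) next
    p <- lombScargle(tp[sel], ibi[sel], freq)
    lf <- bandPower(freq, p, lf_band)
    hf <- bandPower(freq, p, hf_band)
    if (hf < hf_floor) next
    vals[m] <- lf / hf
  }
  minuteSeries(vals, start_min = 0)
}

bandPower <- function(freq, power, band) {
  sel <- freq >= band[1] & freq < band[2]
  if (sum(sel) < 2) return(0)
  pracma::trapz(freq[sel], power[sel])
}

#' Derive the full five-index minute panel from waveforms
#'
#' Runs the complete index derivation: 60-s waveform integration for ICP and
#' mean ABP, CPP as their difference, PRx from 10-s means, beat detection on
#' the ABP waveform, then xBRS and LF/HF from the beat series.  Series are
#' aligned and cropped to the first 72 h.
#'
#' @param abp,icp [WaveformSignal-class] objects.
#' @param patient_id patient identifier.
#' @return A [MinutePanel-class] with attribute `qc` (per-index fraction
#'   missing and the BRS segment acceptance rate).
#' @export
derivePanel <- function(abp, icp, patient_id = "p1") {
  abp_min <- integrate60s(abp)
  icp_min <- integrate60s(icp)
  n <- min(length(abp_min@values), length(icp_min@values))
  trim <- function(s, n) minuteSeries(s@values[seq_len(n)], s@start_min,
                                      s@missing_mask[seq_len(n)])
  abp_min <- trim(abp_min, n); icp_min <- trim(icp_min, n)
  cpp <- computeCPP(abp_min, icp_min)
  prx <- computePRx(abp, icp)
  beats <- detectSystolicPeaks(abp)
  brs <- computeBRS(beats)
  lfhf <- computeLFHF(beats)
  pad <- function(s, n) {
    v <- rep(NA_real_, n)
    k <- min(n, length(s@values))
    v[seq_len(k)] <- s@values[seq_len(k)]
    minuteSeries(v, start_min = 0)
  }
  series <- list(icp = icp_min, cpp = cpp, prx = pad(prx, n),
                 brs = pad(brs, n), lfhf = pad(lfhf, n))
  panel <- cropAlign(series, patient_id = patient_id,
                     total_min = min(n, 4320))
  qc <- vapply(panel@series, function(s) mean(s@missing_mask), numeric(1))
  attr(panel, "qc") <- list(fraction_missing = qc,
                            brs_acceptance = attr(brs, "acceptance_rate"))
  panel
}
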