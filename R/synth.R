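#' Ground-truth parameters for one simulated patient
#'
#' Parameter set for the coupled brain-heart simulator.  Defaults describe a
#' sedated severe-TBI patient with intact baroreflex and balanced
#' sympathovagal tone: heart rate 75 bpm, baroreflex gain 6 ms/mmHg, equal LF
#' and HF interbeat-interval modulation power (LF/HF near 1), ICP 12 mmHg with
#' 2 mmHg slow (B-wave band, 0.3-3 cycles/min) oscillations, and moderate
#' ICP-to-autonomic coupling.
#'
#' @param hr_base baseline heart rate, beats/min (40-140).
#' @param ibi_sd unexplained beat-to-beat interval noise, ms.
#' @param lf_power IBI modulation power near 0.1 Hz, ms^2.
#' @param hf_power IBI modulation power near 0.25 Hz, ms^2.
#' @param baro_gain baroreflex gain, ms/mmHg (>= 0); higher systolic pressure
#'   lengthens the interbeat interval.
#' @param baro_delay baroreflex delay, s.
#' @param sbp_base baseline systolic pressure, mmHg.
#' @param map_base baseline mean arterial pressure, mmHg.
#' @param icp_base baseline intracranial pressure, mmHg.
#' @param icp_slow_amp RMS amplitude of ICP slow waves, mmHg.
#' @param abp_slow_amp RMS amplitude of the slow arterial-pressure component,
#'   mmHg (gives CPP dynamics of its own so CPP is not a mirror image of ICP).
#' @param sbp_noise_sd beat-to-beat systolic pressure noise, mmHg.
#' @param prx_target_sign designed polarity of the slow ABP-to-ICP coupling:
#'   `+1`, `-1` or `0`.
#' @param coupling_lag lag (minutes, may be negative) by which the ICP slow
#'   trend leads the LF/HF modulation; |lag| <= 120 min.
#' @param coupling_strength dimensionless coupling in `[0, 1]`; drives both
#'   the ABP-ICP slow-wave correlation (when `prx_target_sign != 0`) and the
#'   depth of the LF-envelope modulation by the ICP slow trend.
#' @param outcome_label `"favourable"` or `"unfavourable"`.
#' @return A validated list of class `SimPatientParams`.
#' @export
simPatientParams <- function(hr_base = 75, ibi_sd = 5,
                             lf_power = 900, hf_power = 900,
                             baro_gain = 6, baro_delay = 1.5,
                             sbp_base = 120, map_base = 90,
                             icp_base = 12, icp_slow_amp = 2,
                             abp_slow_amp = 3, sbp_noise_sd = 2,
                             prx_target_sign = 1,
                             coupling_lag = 0, coupling_strength = 0.5,
                             outcome_label = "unfavourable") {
  p <- list(hr_base = hr_base, ibi_sd = ibi_sd, lf_power = lf_power,
            hf_power = hf_power, baro_gain = baro_gain,
            baro_delay = baro_delay, sbp_base = sbp_base,
            map_base = map_base, icp_base = icp_base,
            icp_slow_amp = icp_slow_amp, abp_slow_amp = abp_slow_amp,
            sbp_noise_sd = sbp_noise_sd, prx_target_sign = prx_target_sign,
            coupling_lag = coupling_lag,
            coupling_strength = coupling_strength,
            outcome_label = outcome_label)
  if (hr_base < 40 || hr_base > 140)
    stop("hr_base must lie in [40, 140] beats/min")
  if (any(c(sbp_base, map_base, icp_base) <= 0))
    stop("all baseline pressures must be positive")
  if (baro_gain < 0) stop("baro_gain must be >= 0")
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("coupling_strength must lie in [0, 1]")
  if (abs(coupling_lag) > 120)
    stop("|coupling_lag| must be <= 120 min (representable lag range)")
  if (!prx_target_sign %in% c(-1, 0, 1))
    stop("prx_target_sign must be -1, 0 or +1")
  if (!outcome_label %in% c("favourable", "unfavourable"))
    stop("outcome_label must be 'favourable' or 'unfavourable'")
  structure(p, class = "SimPatientParams")
}

# Slow-wave generator: sum of `n_comp` random-frequency sinusoids in the
# 0.3-3 cycles/min band with slowly diffusing phase (coherence time
# `coherence_min`), scaled to unit RMS.  Phase diffusion gives the finite
# autocorrelation time that real B waves have; pure tones would remain
# coherent over hours and produce spurious cross-correlation ridges at large
# lags.  Returns a lookup closure over minutes in [t_from, t_to].
makeSlowWave <- function(t_from, t_to, step_min = 0.1, n_comp = 5,
                         band_cpm = c(0.3, 3), coherence_min = 20) {
  tg <- seq(t_from, t_to, by = step_min)
  freqs <- runif(n_comp, band_cpm[1], band_cpm[2])
  ph0 <- runif(n_comp, 0, 2 * pi)
  s <- numeric(length(tg))
  for (i in seq_len(n_comp)) {
    drift <- cumsum(rnorm(length(tg), sd = sqrt(2 * step_min / coherence_min)))
    s <- s + cos(2 * pi * freqs[i] * tg + ph0[i] + drift)
  }
  s <- s * sqrt(2 / n_comp)  # unit RMS in expectation
  function(t_min) {
    stats::approx(tg, s, xout = t_min, rule = 2)$y
  }
}

# ICP slow component correlated with the shared driver u at polarity `sign`
# and strength `c`; with sign 0 the ICP slow wave is independent of the ABP
# slow wave.
mixSlowComponents <- function(u, v, sign, strength) {
  if (sign == 0) return(v)
  function(t_min) sign * (strength * u(t_min) +
                            sqrt(max(0, 1 - strength^2)) * v(t_min))
}

#' Simulate coupled ABP and ICP waveforms
#'
#' Generates a beat-by-beat arterial pressure waveform (stereotyped pulse
#' template per beat on a slowly varying mean) and a coupled intracranial
#' pressure waveform.  The interbeat interval responds to delayed systolic
#' pressure with gain `baro_gain`, carries LF (0.1 Hz) and HF (0.25 Hz)
#' oscillations of the configured powers plus white noise, and the LF
#' envelope is modulated by the lagged ICP slow wave with depth
#' `coupling_strength`.  Deterministic given `seed`.
#'
#' @param params a [simPatientParams()] object.
#' @param duration_h duration, hours (> 0).
#' @param fs sampling frequency, Hz (>= 50; beat morphology is unresolvable
#'   below that).
#' @param seed integer seed.
#' @param sample_budget refuse simulations needing more samples per channel
#'   than this (guards against accidental multi-gigabyte requests).
#' @return list with elements `abp` and `icp` ([WaveformSignal-class]),
#'   `beat_times` (s), `sbp` and `ibi_ms` (per-beat ground truth).
#' @export
simulateWaveforms <- function(params, duration_h, fs = 100, seed = 1,
                              sample_budget = 1e8) {
  stopifnot(inherits(params, "SimPatientParams"))
  if (duration_h <= 0) stop("duration must be positive")
  if (fs < 50) stop("fs must be >= 50 Hz (beat morphology unresolvable)")
  n_samp <- ceiling(duration_h * 3600 * fs)
  if (n_samp > sample_budget)
    stop(sprintf(
      "requested %d samples per channel exceeds the sample budget of %g",
      n_samp, sample_budget))
  set.seed(seed)
  dur_s <- duration_h * 3600
  dur_min <- duration_h * 60
  margin <- abs(params$coupling_lag) + 5
  u <- makeSlowWave(-margin, dur_min + margin, step_min = 1 / 30)
  v <- makeSlowWave(-margin, dur_min + margin, step_min = 1 / 30)
  s_icp <- mixSlowComponents(u, v, params$prx_target_sign,
                             params$coupling_strength)

  ## --- beat sequence ---
  ibi0 <- 60000 / params$hr_base                   # ms
  d <- max(0L, as.integer(round(params$baro_delay / (ibi0 / 1000))))
  n_max <- ceiling(dur_s / (0.25)) + 10            # hard cap at 250 ms beats
  beat_t <- numeric(n_max); sbp <- numeric(n_max); ibi <- numeric(n_max)
  a_lf <- sqrt(2 * params$lf_power); a_hf <- sqrt(2 * params$hf_power)
  ph_lf <- runif(1, 0, 2 * pi); ph_hf <- runif(1, 0, 2 * pi)
  sbp_noise <- rnorm(n_max, sd = params$sbp_noise_sd)
  ibi_noise <- rnorm(n_max, sd = params$ibi_sd)
  lag_min <- params$coupling_lag
  t_cur <- 0; n <- 0L
  while (t_cur < dur_s) {
    n <- n + 1L
    beat_t[n] <- t_cur
    sbp[n] <- params$sbp_base +
      params$abp_slow_amp * u(t_cur / 60) + sbp_noise[n]
    sbp_d <- if (n > d) sbp[n - d] else params$sbp_base
    env <- max(0, 1 + params$coupling_strength *
                 s_icp(t_cur / 60 - lag_min))
    ibi_n <- ibi0 + params$baro_gain * (sbp_d - params$sbp_base) +
      a_lf * env * sin(2 * pi * 0.10 * t_cur + ph_lf) +
      a_hf * sin(2 * pi * 0.25 * t_cur + ph_hf) +
      ibi_noise[n]
    ibi_n <- min(2000, max(250, ibi_n))
    ibi[n] <- ibi_n
    t_cur <- t_cur + ibi_n / 1000
  }
  beat_t <- beat_t[seq_len(n)]; sbp <- sbp[seq_len(n)]
  ibi <- ibi[seq_len(n)]

  ## --- render waveforms ---
  tg <- seq(0, by = 1 / fs, length.out = n_samp)
  edges <- c(beat_t, t_cur)
  bi <- findInterval(tg, edges, rightmost.closed = FALSE)
  bi[bi < 1L] <- 1L; bi[bi > n] <- n
  x_rel <- tg - edges[bi]                 # seconds since beat onset
  tmpl <- pulseTemplate(x_rel)
  # per-beat template mean over the beat duration, so diastolic pressure can
  # be chosen to hit the target beat mean (MAP)
  T_b <- edges[bi + 1L] - edges[bi]
  m_bar <- (0.5 * PULSE_UP + PULSE_TAU *
              (1 - exp(-(T_b - PULSE_UP) / PULSE_TAU))) / T_b
  sbp_at <- sbp[bi]
  map_at <- params$map_base + params$abp_slow_amp * u(tg / 60)
  pp <- (sbp_at - map_at) / (1 - m_bar)
  abp <- (sbp_at - pp) + pp * tmpl
  icp <- params$icp_base + params$icp_slow_amp * s_icp(tg / 60) + 1.0 * tmpl
  list(abp = waveformSignal(abp, fs = fs, label = "ABP"),
       icp = waveformSignal(icp, fs = fs, label = "ICP"),
       beat_times = beat_t, sbp = sbp, ibi_ms = ibi)
}

# Stereotyped arterial pulse as a function of time since beat onset:
# raised-cosine systolic upstroke of fixed absolute duration (the systolic
# peak sits a constant 120 ms after onset, so measured peak-to-peak
# intervals equal the generated interbeat intervals), then exponential
# diastolic decay.  Normalized to [0, 1].
PULSE_UP <- 0.12   # s, upstroke duration
PULSE_TAU <- 0.20  # s, diastolic decay constant
pulseTemplate <- function(x) {
  y <- numeric(length(x))
  up <- x <= PULSE_UP
  y[up] <- 0.5 * (1 - cos(pi * x[up] / PULSE_UP))
  y[!up] <- exp(-(x[!up] - PULSE_UP) / PULSE_TAU)
  y
}

#' Simulate a minute-resolution index panel directly
#'
#' Fast path that skips waveform synthesis and emits the 1-min series with
#' the same statistical structure the waveform path would yield after index
#' derivation: ICP with slow waves, CPP as the slow arterial mean minus ICP,
#' PRx around `prx_target_sign * coupling_strength`, BRS around `baro_gain`,
#' and an LF/HF series whose fluctuations follow the ICP slow component at
#' lag `coupling_lag` with depth `coupling_strength`.  Deterministic given
#' `seed`.
#'
#' @inheritParams simulateWaveforms
#' @param noise_scale multiplies every minute-level noise term; `0` yields
#'   noise-free series (useful for construction oracles).
#' @return A [MinutePanel-class].
#' @export
simulateMinutePanel <- function(params, duration_h = 72, seed = 1,
                                noise_scale = 1) {
  stopifnot(inherits(params, "SimPatientParams"))
  if (duration_h <= 0 || duration_h > 72)
    stop("duration must lie in (0, 72] h")
  set.seed(seed)
  T <- round(duration_h * 60)
  t_min <- seq_len(T) - 1
  margin <- abs(params$coupling_lag) + 5
  u <- makeSlowWave(-margin, T + margin)
  v <- makeSlowWave(-margin, T + margin)
  s_icp <- mixSlowComponents(u, v, params$prx_target_sign,
                             params$coupling_strength)
  base_ratio <- if (params$hf_power > 0) params$lf_power / params$hf_power
                else 1
  icp <- params$icp_base + params$icp_slow_amp * s_icp(t_min) +
    noise_scale * rnorm(T, sd = 0.5)
  cpp <- params$map_base + params$abp_slow_amp * u(t_min) - icp
  prx <- pmin(0.99, pmax(-0.99,
    params$prx_target_sign * params$coupling_strength +
      noise_scale * rnorm(T, sd = 0.15)))
  brs <- pmax(0, params$baro_gain + noise_scale * rnorm(T, sd = 1))
  env <- pmax(0.05, 1 + params$coupling_strength *
                s_icp(t_min - params$coupling_lag))
  lfhf <- base_ratio * env * exp(noise_scale * rnorm(T, sd = 0.1))
  series <- list(icp = minuteSeries(icp), cpp = minuteSeries(cpp),
                 prx = minuteSeries(prx), brs = minuteSeries(brs),
                 lfhf = minuteSeries(lfhf))
  minutePanel(series, patient_id = "sim")
}

#' Cohort specification for the simulator
#'
#' @param n_patients total number of patients (>= 2; both classes must be
#'   represented).
#' @param class_params named list with elements `favourable` and
#'   `unfavourable`, each a [simPatientParams()] template.
#' @param param_jitter relative spread applied to the physiological magnitude
#'   fields of each patient's parameters (uniform in `1 +/- jitter`).
#' @param duration_h monitoring duration per patient, <= 72 h.
#' @param fidelity `"minute"` (panel fast path) or `"waveform"`.
#' @param fs sampling rate for waveform fidelity, Hz.
#' @param seed integer seed.
#' @return A validated list of class `SimCohortSpec`.
#' @export
simCohortSpec <- function(n_patients,
                          class_params = list(
                            favourable = simPatientParams(
                              outcome_label = "favourable"),
                            unfavourable = simPatientParams(
                              outcome_label = "unfavourable")),
                          param_jitter = 0.1, duration_h = 72,
                          fidelity = c("minute", "waveform"),
                          fs = 100, seed = 1) {
  fidelity <- match.arg(fidelity)
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (duration_h > 72) stop("duration must be <= 72 h")
  if (!all(c("favourable", "unfavourable") %in% names(class_params)))
    stop("class_params must contain 'favourable' and 'unfavourable'")
  structure(list(n_patients = n_patients, class_params = class_params,
                 param_jitter = param_jitter, duration_h = duration_h,
                 fidelity = fidelity, fs = fs, seed = seed),
            class = "SimCohortSpec")
}

JITTER_FIELDS <- c("hr_base", "lf_power", "hf_power", "baro_gain",
                   "sbp_base", "map_base", "icp_base", "icp_slow_amp",
                   "abp_slow_amp")

#' Simulate a labelled patient cohort
#'
#' Draws per-patient parameters from the class templates with multiplicative
#' jitter on the physiological magnitude fields (the designed coupling lag,
#' polarity and strength are kept exact — they are the class signal), samples
#' CRASH-style clinical metadata carrying no class information, and generates
#' a panel (or waveform pair) per patient.  Reproducible given the spec seed.
#'
#' Metadata distributions: age normal(46, 16) clipped to 18-85; GCS uniform
#' on 3-12; pupil reactivity bilateral/unilateral/nonreactive with
#' probabilities 0.76/0.18/0.06; major extracranial injury with probability
#' 0.4.
#'
#' @param spec a [simCohortSpec()].
#' @return list with `records` (data.frame: patient_id, age, gcs, pupils,
#'   extracranial, outcome_short, outcome_long), `panels` (named list of
#'   [MinutePanel-class], minute fidelity) or `waveforms` (waveform
#'   fidelity), and `params` (per-patient ground truth).
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "SimCohortSpec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  n_unf <- floor(n / 2)
  classes <- c(rep("favourable", n - n_unf), rep("unfavourable", n_unf))
  if (!all(c("favourable", "unfavourable") %in% classes))
    stop("both classes must receive at least one patient")
  ids <- sprintf("P%03d", seq_len(n))
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  age <- pmin(85, pmax(18, round(rnorm(n, 46, 16))))
  gcs <- sample(3:12, n, replace = TRUE)
  pupils <- sample(c("bilateral", "unilateral", "nonreactive"), n,
                   replace = TRUE, prob = c(0.76, 0.18, 0.06))
  extracranial <- runif(n) < 0.4
  records <- data.frame(patient_id = ids, age = age, gcs = gcs,
                        pupils = pupils, extracranial = extracranial,
                        outcome_short = ifelse(classes == "favourable",
                                               "fav", "unfav"),
                        outcome_long = ifelse(classes == "favourable",
                                              "fav", "unfav"),
                        stringsAsFactors = FALSE)
  params <- vector("list", n); names(params) <- ids
  out <- vector("list", n); names(out) <- ids
  for (i in seq_len(n)) {
    tpl <- spec$class_params[[classes[i]]]
    p <- unclass(tpl)
    set.seed(seeds[2L * i - 1L])
    for (f in JITTER_FIELDS)
      p[[f]] <- p[[f]] * runif(1, 1 - spec$param_jitter,
                               1 + spec$param_jitter)
    p$outcome_label <- classes[i]
    pp <- do.call(simPatientParams, p)
    params[[i]] <- pp
    if (spec$fidelity == "minute") {
      pan <- simulateMinutePanel(pp, duration_h = spec$duration_h,
                                 seed = seeds[2L * i])
      pan@patient_id <- ids[i]
      out[[i]] <- pan
    } else {
      out[[i]] <- simulateWaveforms(pp, duration_h = spec$duration_h,
                                    fs = spec$fs, seed = seeds[2L * i])
    }
  }
  res <- list(records = records, params = params)
  if (spec$fidelity == "minute") res$panels <- out else res$waveforms <- out
  res
}
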