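test_that("systolic peak detection recovers beat count and intervals", {
  p <- simPatientParams(hr_base = 60, ibi_sd = 0, lf_power = 0,
                        hf_power = 0, sbp_noise_sd = 0, baro_gain = 0,
                        coupling_strength = 0)
  wf <- simulateWaveforms(p, duration_h = 120 / 3600, fs = 100, seed = 1)
  b <- detectSystolicPeaks(wf$abp)
  expect_true(abs(length(b@peak_times) - 120) <= 1)
  expect_lt(abs(median(b@ibi_ms, na.rm = TRUE) - 1000), 5)
  expect_error(detectSystolicPeaks(waveformSignal(rep(80, 6000), fs = 100)),
               "<2 peaks")
  expect_error(detectSystolicPeaks(waveformSignal(1:100, fs = 20)), ">= 50")
})

test_that("detected beats reflect the planted baroreflex coupling", {
  p <- simPatientParams(baro_gain = 6, ibi_sd = 0, lf_power = 0,
                        hf_power = 0, baro_delay = 1.5,
                        coupling_strength = 0)
  wf <- simulateWaveforms(p, duration_h = 0.1, fs = 100, seed = 2)
  b <- detectSystolicPeaks(wf$abp)
  n <- length(b@peak_times)
  # interval lengthens ~2 beats after a pressure rise: positive lagged
  # correlation between SBP and IBI
  r <- cor(b@sbp[1:(n - 2)], b@ibi_ms[3:n], use = "complete.obs")
  expect_gt(r, 0.5)
})

test_that("CPP is the element-wise ABP-ICP difference with missingness", {
  abp <- minuteSeries(c(80, 85, NA, 90))
  icp <- minuteSeries(c(10, NA, 12, 15))
  cpp <- computeCPP(abp, icp)
  expect_equal(seriesValues(cpp), c(70, NA, NA, 75))
  expect_error(computeCPP(abp, minuteSeries(1:3)), "lengths differ")
  set.seed(3)
  a <- rnorm(50, 85, 4); i <- rnorm(50, 12, 2)
  expect_equal(seriesValues(computeCPP(minuteSeries(a), minuteSeries(i))),
               a - i)
})

test_that("PRx saturates at +/-1 for perfectly coupled slow components", {
  set.seed(4)
  slow <- rep(rnorm(120), each = 10 * 50)      # 10-s constant blocks
  abp <- waveformSignal(80 + slow + rnorm(length(slow), 0, 0.01), fs = 50)
  icp_pos <- waveformSignal(12 + slow, fs = 50)
  icp_neg <- waveformSignal(12 - slow, fs = 50)
  expect_gt(min(seriesValues(computePRx(abp, icp_pos)), na.rm = TRUE), 0.95)
  expect_lt(max(seriesValues(computePRx(abp, icp_neg)), na.rm = TRUE), -0.95)
})

test_that("PRx equals the brute-force recomputation on gap-free input", {
  p <- simPatientParams(prx_target_sign = 1, coupling_strength = 0.7)
  wf <- simulateWaveforms(p, duration_h = 0.5, fs = 50, seed = 5)
  fast <- seriesValues(computePRx(wf$abp, wf$icp))
  slow <- brutePRx(wf$abp, wf$icp)
  expect_lt(max(abs(fast - slow), na.rm = TRUE), 1e-10)
})

test_that("zero-variance PRx windows are missing, not zero", {
  abp <- waveformSignal(rep(80, 50 * 600), fs = 50)
  icp <- waveformSignal(12 + rnorm(50 * 600), fs = 50)
  v <- seriesValues(computePRx(abp, icp))
  expect_true(all(is.na(v)))
})

test_that("xBRS recovers a planted gain and its delay", {
  clean <- simPatientParams(baro_gain = 6, ibi_sd = 0, lf_power = 0,
                            hf_power = 0, sbp_noise_sd = 0,
                            coupling_strength = 0)
  wf <- simulateWaveforms(clean, duration_h = 0.25, fs = 100, seed = 6)
  brs <- computeBRS(detectSystolicPeaks(wf$abp))
  est <- median(seriesValues(brs), na.rm = TRUE)
  expect_lt(abs(est - 6) / 6, 0.10)
  expect_true(all(seriesValues(brs) >= 0, na.rm = TRUE))

  delayed <- simPatientParams(baro_gain = 6, ibi_sd = 0, lf_power = 0,
                              hf_power = 0, sbp_noise_sd = 0,
                              baro_delay = 2, coupling_strength = 0)
  wf2 <- simulateWaveforms(delayed, duration_h = 0.25, fs = 100, seed = 7)
  brs2 <- computeBRS(detectSystolicPeaks(wf2$abp))
  expect_lt(abs(median(seriesValues(brs2), na.rm = TRUE) - 6) / 6, 0.10)
})

test_that("LF/HF separates band-assigned modulations", {
  base <- list(baro_gain = 0, ibi_sd = 0, sbp_noise_sd = 0,
               coupling_strength = 0)
  # pure 0.10 Hz: ratio far above 1 (broadband floor only in HF)
  p_lf <- do.call(simPatientParams, c(base, list(lf_power = 900,
                                                 hf_power = 0)))
  wf <- simulateWaveforms(p_lf, duration_h = 0.25, fs = 100, seed = 8)
  v <- seriesValues(computeLFHF(detectSystolicPeaks(wf$abp)))
  expect_gte(median(v, na.rm = TRUE), 10)
  # equal power at 0.10 and 0.25 Hz: ratio near 1
  p_eq <- do.call(simPatientParams, c(base, list(lf_power = 900,
                                                 hf_power = 900)))
  wf2 <- simulateWaveforms(p_eq, duration_h = 0.25, fs = 100, seed = 9)
  v2 <- seriesValues(computeLFHF(detectSystolicPeaks(wf2$abp)))
  expect_lt(abs(median(v2, na.rm = TRUE) - 1), 0.15)
  # HF-only modulation: ratio far below 1
  p_hf <- do.call(simPatientParams, c(base, list(lf_power = 0,
                                                 hf_power = 900)))
  wf3 <- simulateWaveforms(p_hf, duration_h = 0.25, fs = 100, seed = 10)
  v3 <- seriesValues(computeLFHF(detectSystolicPeaks(wf3$abp)))
  expect_lte(median(v3, na.rm = TRUE), 0.1)
})

test_that("Lomb-Scargle reduces to the classical periodogram when even", {
  set.seed(11)
  n <- 256
  dt <- 0.8
  t <- (0:(n - 1)) * dt
  y <- rnorm(n)
  # Fourier frequencies (excluding DC and Nyquist)
  k <- 1:(n / 2 - 1)
  freq <- k / (n * dt)
  ls <- lombScargle(t, y, freq)
  yc <- y - mean(y)
  classical <- (Mod(fft(yc))^2 / n)[k + 1]
  expect_lt(max(abs(ls - classical) / classical), 1e-6)
})
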