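test_that("column lags span the +/-120-min range", {
  expect_equal(columnLag(0, 240), -120)
  expect_equal(columnLag(120, 240), 0)
  expect_equal(columnLag(239, 240), 119)
  expect_error(columnLag(240, 240), "out of range")
  expect_error(columnLag(-1, 240), "out of range")
})

test_that("geometry validation enforces the published grids in paper mode", {
  expect_error(wtlccParams(J = 239), "even")
  expect_error(wtlccParams(N = 100, K = 200), "N >= K")
  expect_error(wtlccParams(N = 100, K = 33), "divide")
  expect_silent(wtlccParams(N = 1080, S = 90, K = 60, paper_mode = TRUE))
  expect_error(wtlccParams(N = 500, S = 90, K = 50, paper_mode = TRUE),
               "360, 720, 1080")
  expect_error(wtlccParams(N = 1080, S = 90, K = 60, J = 120,
                           paper_mode = TRUE), "fixed at 240")
})

test_that("self-correlation puts 1 in the zero-lag column", {
  s <- randomSeries(600, seed = 1)
  prm <- wtlccParams(N = 240, S = 60, K = 20, J = 40)
  m <- buildMatrix(s, s, start = 100, params = prm)
  expect_equal(unname(matrixValues(m)[, 20 + 1]), rep(1, 20),
               tolerance = 1e-12)
})

test_that("a pure delay moves the per-row argmax to that lag", {
  set.seed(2)
  x <- as.numeric(stats::filter(rnorm(800), rep(1, 5), sides = 1))
  x[is.na(x)] <- 0
  I1 <- minuteSeries(x)
  I2 <- minuteSeries(c(rep(0, 30), x[1:770]))   # I2 = I1 delayed 30 min
  prm <- wtlccParams(N = 300, S = 60, K = 20, J = 120)
  m <- buildMatrix(I1, I2, start = 200, params = prm)
  lag_at_max <- columnLag(apply(matrixValues(m), 1, which.max) - 1, 120)
  expect_gte(mean(lag_at_max == 30), 0.95)
})

test_that("every entry matches the naive double-loop oracle", {
  s1 <- randomSeries(700, seed = 3, mean = 12, sd = 2)
  s2 <- randomSeries(700, seed = 4, mean = 1, sd = 0.3)
  prm <- wtlccParams(N = 240, S = 60, K = 30, J = 80)
  m <- buildMatrix(s1, s2, start = 150, params = prm)
  oracle <- naiveWTLCC(seriesValues(s1), seriesValues(s2), start = 150,
                       N = 240, S = 60, K = 30, J = 80)
  expect_identical(is.na(matrixValues(m)), is.na(oracle))
  expect_lt(max(abs(matrixValues(m) - oracle), na.rm = TRUE), 1e-10)
})

test_that("oracle equivalence holds with gaps and at the series edges", {
  set.seed(5)
  v <- rnorm(500)
  v[sample(500, 60)] <- NA
  s1 <- minuteSeries(v)
  s2 <- randomSeries(500, seed = 6)
  prm <- wtlccParams(N = 200, S = 50, K = 20, J = 60, min_valid_frac = 0.8)
  m <- buildMatrix(s1, s2, start = 0, params = prm)   # left edge
  oracle <- naiveWTLCC(seriesValues(s1), seriesValues(s2), 0,
                       200, 50, 20, 60)
  expect_identical(is.na(matrixValues(m)), is.na(oracle))
  expect_lt(max(abs(matrixValues(m) - oracle), na.rm = TRUE), 1e-10)
})

test_that("swapping the pair negates the lag once windows are re-anchored", {
  # the pair (I1[t], I2[t+l]) over window W equals the pair
  # (I2[u], I1[u-l]) over the window W+l, so swapping the series mirrors the
  # lag axis provided the analysis window moves with the lag
  s1 <- randomSeries(600, seed = 7)
  s2 <- randomSeries(600, seed = 8)
  prm <- wtlccParams(N = 200, S = 50, K = 10, J = 60)
  ab <- matrixValues(buildMatrix(s1, s2, 200, prm))
  for (l in c(-20, -7, 0, 13)) {
    ba <- matrixValues(buildMatrix(s2, s1, 200 + l, prm))
    expect_equal(ab[, l + 30 + 1], ba[, -l + 30 + 1], tolerance = 1e-10)
  }
})

test_that("shifting both series shifts window starts and nothing else", {
  s1 <- randomSeries(600, seed = 9)
  s2 <- randomSeries(600, seed = 10)
  d <- 37
  s1d <- minuteSeries(s1@values, start_min = d)
  s2d <- minuteSeries(s2@values, start_min = d)
  prm <- wtlccParams(N = 200, S = 50, K = 10, J = 60)
  m0 <- buildMatrix(s1, s2, 150, prm)
  md <- buildMatrix(s1d, s2d, 150 + d, prm)
  expect_equal(matrixValues(m0), matrixValues(md), tolerance = 1e-12)
  expect_equal(matrixWindowStart(md), 150 + d)
})

test_that("matrix extraction counts follow floor((T-N)/S)+1", {
  p <- simPatientParams()
  pan <- simulateMinutePanel(p, duration_h = 72, seed = 11)
  prm90 <- wtlccParams(N = 1080, S = 90, K = 15, J = 240)
  expect_length(extractMatrices(pan, c("icp", "lfhf"), prm90), 37)
  prm15 <- wtlccParams(N = 1080, S = 15, K = 15, J = 240)
  expect_length(extractMatrices(pan, c("icp", "lfhf"), prm15), 217)
  # T = N: exactly one placement
  pan1 <- simulateMinutePanel(p, duration_h = 18, seed = 12)
  expect_length(extractMatrices(pan1, c("icp", "lfhf"), prm90), 1)
  # T < N: empty with a warning
  pan2 <- simulateMinutePanel(p, duration_h = 10, seed = 13)
  expect_warning(out <- extractMatrices(pan2, c("icp", "lfhf"), prm90),
                 "shorter")
  expect_length(out, 0)
})

test_that("degenerate windows are refused or flagged", {
  s <- randomSeries(300, seed = 14)
  expect_error(buildMatrix(s, s, 0, wtlccParams(N = 100, K = 50, J = 20)),
               "sub-window")
  # constant I1 within a row: that row is all-missing
  v <- rnorm(300); v[101:120] <- 5
  m <- buildMatrix(minuteSeries(v), s, 100,
                   wtlccParams(N = 40, S = 10, K = 2, J = 10))
  expect_true(all(is.na(matrixValues(m)[1, ])))
  expect_false(all(is.na(matrixValues(m)[2, ])))
})

test_that("all emitted entries lie in [-1, 1]", {
  for (seed in 1:5) {
    s1 <- randomSeries(400, seed = seed)
    s2 <- randomSeries(400, seed = seed + 100)
    m <- matrixValues(buildMatrix(s1, s2, 50,
                                  wtlccParams(N = 300, S = 50, K = 30,
                                              J = 60)))
    expect_true(all(abs(m[!is.na(m)]) <= 1))
  }
})
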