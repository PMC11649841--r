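test_that("outcome dichotomization follows the GOS / GOS-E cutoffs", {
  expect_equal(dichotomize("GOS", 4), "fav")
  expect_equal(dichotomize("GOS", 5), "fav")
  expect_equal(dichotomize("GOS", 1), "unfav")
  expect_equal(dichotomize("GOS", 3), "unfav")
  expect_equal(dichotomize("GOSE", 4), "unfav")
  expect_equal(dichotomize("GOSE", 5), "fav")
  expect_equal(dichotomize("GOSE", 8), "fav")
  expect_equal(dichotomize("GOS", c(1, 4, 5)), c("unfav", "fav", "fav"))
  expect_error(dichotomize("GOS", 6), "1-5")
  expect_error(dichotomize("GOSE", 0), "1-8")
})

test_that("classification report handles separation, ties and counts", {
  r <- classificationReport(c(0.9, 0.8, 0.1, 0.2),
                            c("unfav", "unfav", "fav", "fav"))
  expect_equal(r$auc, 1)
  expect_equal(r$accuracy, 1)
  expect_equal(r$f1, 1)
  expect_equal(sum(r$confusion), r$n_patients)
  # complete ties: AUC 0.5
  r2 <- classificationReport(rep(0.4, 6), rep(c("fav", "unfav"), 3))
  expect_equal(r2$auc, 0.5)
  # threshold is strict: score == threshold predicts favourable
  r3 <- suppressWarnings(
    classificationReport(c(0.5, 0.6), c("unfav", "unfav")))
  expect_equal(unname(r3$confusion["unfav", "fav"]), 1L)
  expect_error(classificationReport(numeric(0), character(0)), "empty")
})

test_that("confusion counts conserve n across thresholds", {
  set.seed(1)
  s <- runif(40)
  y <- rep(c("fav", "unfav"), 20)
  for (thr in c(0.2, 0.5, 0.8))
    expect_equal(sum(classificationReport(s, y, thr)$confusion), 40L)
})

test_that("rank AUC is monotone-invariant and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(2)
  s <- rnorm(60)
  y <- rbinom(60, 1, 0.5)
  a1 <- aucRank(s, y)
  expect_equal(aucRank(exp(s), y), a1)         # strictly monotone transform
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(a1, ref, tolerance = 1e-12)
})

test_that("null scores give AUC near 0.5", {
  set.seed(3)
  aucs <- replicate(20, aucRank(runif(200), rep(c(0, 1), 100)))
  expect_true(all(abs(aucs - 0.5) < 0.12))
})

test_that("identical class samples give Mann-Whitney p near 1", {
  f <- data.frame(x = rep(c(1, 2, 3, 4, 5, 6), 2))
  y <- rep(c("fav", "unfav"), each = 6)
  out <- cohortCompare(f, y)
  expect_gt(out$p_value[1], 0.9)
})

test_that("exact Mann-Whitney matches full enumeration for small groups", {
  g0 <- c(1, 2, 3); g1 <- c(10, 11, 12)
  out <- cohortCompare(data.frame(x = c(g0, g1)),
                       c(rep("fav", 3), rep("unfav", 3)))
  # enumerate all 20 assignments of 6 values into two groups of 3 and count
  # arrangements with U as or more extreme (two-sided)
  vals <- c(g0, g1)
  combs <- utils::combn(6, 3)
  U <- apply(combs, 2, function(ix) {
    a <- vals[ix]; b <- vals[-ix]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  })
  u_obs <- sum(outer(g0, g1, ">"))
  p_exact <- mean(pmin(U, 9 - U) <= min(u_obs, 9 - u_obs))
  expect_equal(out$p_value[1], p_exact, tolerance = 1e-12)
  expect_match(out$test[1], "exact")
})

test_that("Fisher fallback matches the hypergeometric for a diagonal table", {
  f <- data.frame(g = rep(c("a", "b"), each = 10))
  y <- rep(c("fav", "unfav"), each = 10)
  out <- cohortCompare(f, y)
  expect_equal(out$test[1], "Fisher exact")
  # P(table as extreme) for [[10,0],[0,10]]: both diagonal extremes
  p_hyper <- 2 * stats::dhyper(10, 10, 10, 10)
  expect_equal(out$p_value[1], p_hyper, tolerance = 1e-12)
})

test_that("cohort comparison formats medians and refuses empty classes", {
  set.seed(4)
  f <- data.frame(icp = rnorm(20, 12), cpp = rnorm(20, 72))
  y <- rep(c("fav", "unfav"), 10)
  out <- cohortCompare(f, y)
  expect_equal(nrow(out), 2)
  expect_match(out$favourable[1], "^[0-9.]+ \\([0-9.]+-[0-9.]+\\)$")
  expect_false(anyNA(out$shapiro_p))
  expect_error(cohortCompare(f, rep("unfav", 20)), "2 patients")
})

test_that("PNG renderers write heatmap, ROC and confusion files", {
  dir <- withr::local_tempdir()
  m <- buildMatrix(randomSeries(300, 1), randomSeries(300, 2), 50,
                   wtlccParams(N = 200, S = 50, K = 10, J = 40))
  f1 <- file.path(dir, "m.png")
  plotMatrix(m, f1)
  scores <- c(0.9, 0.8, 0.3, 0.2)
  labels <- c("unfav", "unfav", "fav", "fav")
  f2 <- file.path(dir, "roc.png")
  plotROC(scores, labels, f2)
  f3 <- file.path(dir, "conf.png")
  plotConfusion(classificationReport(scores, labels), f3)
  expect_true(all(file.exists(f1, f2, f3)))
  expect_true(all(file.size(c(f1, f2, f3)) > 0))
})
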