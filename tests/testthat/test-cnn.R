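# tiny matrices for shape/aggregation contracts: 12x16 with a planted
# class-dependent stripe
tinyMatrices <- function(n_per_class = 6, seed = 1) {
  set.seed(seed)
  out <- list(); labels <- c()
  for (i in seq_len(2 * n_per_class)) {
    cls <- if (i <= n_per_class) 0 else 1
    v <- matrix(rnorm(12 * 16, 0, 0.2), 12, 16)
    v[, 4 + cls * 8] <- v[, 4 + cls * 8] + 0.8
    v[] <- pmin(1, pmax(-1, v))
    pid <- sprintf("p%02d", i)
    out[[i]] <- new("WTLCCMatrix", values = v, patient_id = pid,
                    window_start = 0, params = list(K = 12, J = 16),
                    pair = c("icp", "lfhf"))
    labels[pid] <- if (cls == 0) "fav" else "unfav"
  }
  list(matrices = out, labels = labels)
}

test_that("patient split groups by id and keeps both classes", {
  labels <- setNames(rep(c("fav", "unfav"), each = 10),
                     sprintf("P%02d", 1:20))
  sp <- patientSplit(labels, val_frac = 0.3, seed = 2)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_setequal(c(sp$train, sp$val), names(labels))
  expect_setequal(unique(labels[sp$val]), c("fav", "unfav"))
  expect_setequal(unique(labels[sp$train]), c("fav", "unfav"))
})

test_that("training errors on degenerate inputs", {
  tm <- tinyMatrices()
  cfg <- tinyCNNConfig(epochs = 1)
  one_class <- setNames(rep("fav", length(tm$labels)), names(tm$labels))
  expect_error(trainScorer(tm$matrices, one_class, cfg), "single class")
  expect_error(trainScorer(tm$matrices, tm$labels[1:3], cfg), "label")
})

test_that("training is deterministic given the seed", {
  tm <- tinyMatrices()
  cfg <- tinyCNNConfig(seed = 5, epochs = 3)
  m1 <- trainScorer(tm$matrices, tm$labels, cfg)
  m2 <- trainScorer(tm$matrices, tm$labels, cfg)
  expect_identical(scoreMatrices(m1, tm$matrices),
                   scoreMatrices(m2, tm$matrices))
})

test_that("scores are probabilities and the net learns a simple stripe", {
  tm <- tinyMatrices(n_per_class = 12, seed = 3)
  cfg <- tinyCNNConfig(seed = 1, epochs = 30)
  model <- trainScorer(tm$matrices, tm$labels, cfg)
  s <- scoreMatrices(model, tm$matrices)
  expect_true(all(s >= 0 & s <= 1))
  y <- as.numeric(tm$labels[vapply(tm$matrices, matrixPatient,
                                   character(1))] == "unfav")
  expect_gt(aucRank(s, y), 0.9)
})

test_that("patient aggregation is the mean with a strict 0.5 rule", {
  tm <- tinyMatrices()
  model <- trainScorer(tm$matrices, tm$labels, tinyCNNConfig(epochs = 1))
  # aggregation contract on synthetic per-matrix scores via a stub model:
  # check the documented rule directly
  agg <- function(scores) list(score = mean(scores),
                               label = if (mean(scores) > 0.5) "unfav"
                                       else "fav")
  expect_equal(agg(c(0.6, 0.7, 0.8))$score, 0.7)
  expect_equal(agg(c(0.6, 0.7, 0.8))$label, "unfav")
  expect_equal(agg(c(0.5, 0.5))$label, "fav")      # strict "exceeds"
  expect_equal(agg(0.2)$label, "fav")
  # and that scorePatient implements exactly that rule
  sp <- scorePatient(model, tm$matrices[1:3])
  expect_equal(sp$score, mean(scoreMatrices(model, tm$matrices[1:3])))
  expect_equal(sp$label, if (sp$score > 0.5) "unfav" else "fav")
  expect_error(scorePatient(model, list()), "no matrices")
})

test_that("patient score is invariant to matrix order", {
  tm <- tinyMatrices()
  model <- trainScorer(tm$matrices, tm$labels, tinyCNNConfig(epochs = 2))
  s1 <- scorePatient(model, tm$matrices[c(1, 2, 3)])$score
  s2 <- scorePatient(model, tm$matrices[c(3, 1, 2)])$score
  expect_equal(s1, s2)
})

test_that("embeddings have the configured length and mean aggregation", {
  tm <- tinyMatrices()
  cfg <- tinyCNNConfig(epochs = 2)
  model <- trainScorer(tm$matrices, tm$labels, cfg)
  e1 <- embedPatient(model, tm$matrices[1])
  expect_length(e1, cfg$dense_width)
  # duplicated matrix: patient embedding equals the single-matrix embedding
  e2 <- embedPatient(model, tm$matrices[c(1, 1)])
  expect_equal(e1, e2)
})

test_that("shape mismatches with the fitted model are refused", {
  tm <- tinyMatrices()
  model <- trainScorer(tm$matrices, tm$labels, tinyCNNConfig(epochs = 1))
  other <- new("WTLCCMatrix", values = matrix(0, 6, 6), patient_id = "x",
               window_start = 0, params = list(K = 6, J = 6),
               pair = c("a", "b"))
  expect_error(scoreMatrices(model, list(other)), "shape")
  expect_error(embedPatient(model, list(other)), "shape")
})
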