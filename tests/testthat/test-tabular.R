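mkRecords <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             age = round(runif(n, 20, 80)),
             gcs = sample(3:12, n, replace = TRUE),
             pupils = sample(c("bilateral", "unilateral", "nonreactive"),
                             n, replace = TRUE),
             extracranial = sample(c(TRUE, FALSE), n, replace = TRUE),
             outcome_short = rep(c("fav", "unfav"), length.out = n),
             outcome_long = rep(c("fav", "unfav"), length.out = n),
             stringsAsFactors = FALSE)
}

constPanel <- function(pid, icp = 12, n = 60) {
  series <- list(icp = minuteSeries(rep(icp, n)),
                 cpp = minuteSeries(rep(70, n)),
                 prx = minuteSeries(rep(0.2, n)),
                 brs = minuteSeries(rep(6, n)),
                 lfhf = minuteSeries(rep(1, n)))
  minutePanel(series, patient_id = pid)
}

test_that("averaged features are panel means plus encoded covariates", {
  rec <- mkRecords(4)
  panels <- setNames(lapply(rec$patient_id, constPanel), rec$patient_id)
  tab <- buildFeatures(rec, panels = panels, mode = "averages")
  expect_equal(nrow(tab), 4)
  expect_equal(tab$icp, rep(12, 4))
  expect_equal(tab$cpp, rep(70, 4))
  expect_true(all(tab$pupils %in% 0:2))
  expect_setequal(setdiff(names(tab), c("patient_id", "label")),
                  c("icp", "cpp", "prx", "brs", "lfhf",
                    "age", "gcs", "pupils", "extracranial"))
})

test_that("missing-covariate patients are dropped with the quoted bookkeeping", {
  rec <- mkRecords(100)
  rec$gcs[1:5] <- NA                       # 5 missing GCS
  rec$pupils[6:8] <- NA                    # 3 missing pupils, disjoint
  panels <- setNames(lapply(rec$patient_id, constPanel), rec$patient_id)
  tab <- buildFeatures(rec, panels = panels, mode = "averages")
  expect_equal(nrow(tab), 92)
  expect_length(attr(tab, "excluded"), 8)
})

test_that("an index with no valid minutes excludes the patient with reason", {
  rec <- mkRecords(2)
  panels <- setNames(lapply(rec$patient_id, constPanel), rec$patient_id)
  panels[[1]]@series$brs <- minuteSeries(rep(NA_real_, 60))
  tab <- buildFeatures(rec, panels = panels, mode = "averages")
  expect_equal(nrow(tab), 1)
  expect_match(attr(tab, "excluded"), "brs")
})

test_that("embedding features have embedding_dim + 4 columns", {
  co <- separableCohort(n_patients = 8, duration_h = 6, seed = 3)
  prm <- wtlccParams(N = 240, S = 60, K = 15, J = 120)
  mbp <- lapply(co$panels, extractMatrices, pair = c("icp", "lfhf"),
                params = prm)
  labels <- setNames(co$records$outcome_short, co$records$patient_id)
  cfg <- tinyCNNConfig(epochs = 2)
  scorer <- trainScorer(unlist(mbp, recursive = FALSE), labels, cfg)
  tab <- buildFeatures(co$records, mode = "embeddings", scorer = scorer,
                       matrices_by_patient = mbp)
  expect_equal(ncol(tab) - 2, cfg$dense_width + 4)   # minus id and label
})

test_that("the booster separates a trivially separable feature", {
  rec <- mkRecords(40)
  tab <- data.frame(patient_id = rec$patient_id,
                    x = ifelse(rec$outcome_short == "unfav", 1, 0),
                    label = rec$outcome_short, stringsAsFactors = FALSE)
  fit <- fitEvaluate(tab[1:24, ], tab[25:40, ], seed = 1)
  expect_equal(fit$report$auc, 1)
})

test_that("permuted labels give chance-level booster AUC", {
  set.seed(9)
  n <- 60
  tab <- data.frame(patient_id = sprintf("Q%03d", 1:n),
                    x1 = rnorm(n), x2 = rnorm(n),
                    label = sample(rep(c("fav", "unfav"), n / 2)),
                    stringsAsFactors = FALSE)
  aucs <- vapply(1:3, function(s)
    fitEvaluate(tab[1:40, ], tab[41:n, ], seed = s)$report$auc, numeric(1))
  expect_true(mean(aucs) > 0.2 && mean(aucs) < 0.8)
})

test_that("mismatched columns and shared patients are refused", {
  tab1 <- data.frame(patient_id = c("a", "b", "c", "d"), x = 1:4,
                     label = c("fav", "unfav", "fav", "unfav"),
                     stringsAsFactors = FALSE)
  tab2 <- data.frame(patient_id = c("e", "f"), z = 1:2,
                     label = c("fav", "unfav"), stringsAsFactors = FALSE)
  expect_error(fitEvaluate(tab1, tab2), "z")
  tab3 <- tab1[3:4, ]
  expect_error(fitEvaluate(tab1, tab3), "share")
  tab4 <- data.frame(patient_id = c("e", "f"), x = 1:2,
                     label = c("fav", "unfav"), stringsAsFactors = FALSE)
  expect_error(fitEvaluate(tab1[c(1, 3), ], tab4), "single class")
})
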