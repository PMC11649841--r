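#' Build a per-patient feature table
#'
#' One row per patient, combining one of two feature sets with the CRASH
#' clinical covariates (age, GCS, pupil reactivity encoded ordinally
#' 0 = bilateral / 1 = unilateral / 2 = nonreactive, major extracranial
#' injury 0/1):
#'
#' * `"averages"` — the mean of each neuromonitoring index (ICP, CPP, PRx,
#'   BRS, LF/HF) over its non-missing minutes of the first 72 h;
#' * `"embeddings"` — the patient-level CNN embedding from
#'   [embedPatient()].
#'
#' Patients with a missing covariate, or (in averages mode) an index with no
#' valid minutes, are excluded; the excluded ids and reasons are kept in the
#' `excluded` attribute.
#'
#' @param records data.frame of patient metadata (columns `patient_id`,
#'   `age`, `gcs`, `pupils`, `extracranial` and an outcome column).
#' @param panels named list of [MinutePanel-class] (averages mode).
#' @param mode `"averages"` or `"embeddings"`.
#' @param scorer a [TrainedScorer-class] (embeddings mode).
#' @param matrices_by_patient named list of per-patient
#'   [WTLCCMatrix-class] lists (embeddings mode).
#' @param outcome which outcome column to use as the label
#'   (default `"outcome_short"`).
#' @return data.frame with one row per retained patient, a `label` column,
#'   and attribute `excluded`.
#' @export
buildFeatures <- function(records, panels = NULL,
                          mode = c("averages", "embeddings"),
                          scorer = NULL, matrices_by_patient = NULL,
                          outcome = "outcome_short") {
  mode <- match.arg(mode)
  if (mode == "embeddings" && (is.null(scorer) || is.null(matrices_by_patient)))
    stop("embeddings mode requires a fitted scorer and per-patient matrices")
  if (mode == "averages" && is.null(panels))
    stop("averages mode requires panels")
  excluded <- character()
  rows <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    pid <- rec$patient_id
    cov <- c(age = rec$age, gcs = rec$gcs,
             pupils = encodePupils(rec$pupils),
             extracranial = as.numeric(rec$extracranial))
    if (anyNA(cov)) {
      nm <- names(cov)[is.na(cov)][1]
      excluded <- c(excluded, sprintf("%s: missing covariate %s", pid, nm))
      next
    }
    if (mode == "averages") {
      pan <- panels[[pid]]
      if (is.null(pan)) {
        excluded <- c(excluded, sprintf("%s: no panel", pid)); next
      }
      feats <- vapply(PANEL_INDICES, function(nm) {
        v <- seriesValues(panelSeries(pan, nm))
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      }, numeric(1))
      if (anyNA(feats)) {
        nm <- names(feats)[is.na(feats)][1]
        excluded <- c(excluded,
                      sprintf("%s: index %s has no valid minutes", pid, nm))
        next
      }
    } else {
      ml <- matrices_by_patient[[pid]]
      if (is.null(ml) || length(ml) == 0) {
        excluded <- c(excluded, sprintf("%s: no matrices", pid)); next
      }
      feats <- embedPatient(scorer, ml)
      names(feats) <- sprintf("emb%03d", seq_along(feats))
    }
    rows[[pid]] <- data.frame(patient_id = pid, t(feats), t(cov),
                              label = rec[[outcome]],
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

encodePupils <- function(p) {
  map <- c(bilateral = 0, unilateral = 1, nonreactive = 2)
  unname(map[as.character(p)])
}

#' Fit and evaluate the gradient-boosted comparison model
#'
#' Gradient-boosted trees (XGBoost, logistic objective) on a feature table,
#' with declared defaults: depth 3, learning rate 0.1, up to 200 rounds with
#' early stopping on validation log-loss.  The train/validation patient
#' partition must be patient-disjoint and is reused from the CNN run, never
#' re-drawn.
#'
#' @param table_train,table_val feature tables from [buildFeatures()] with
#'   identical feature columns and disjoint patients.
#' @param seed integer seed.
#' @param nrounds,max_depth,eta booster hyperparameters.
#' @return list: `report` (an `EvalReport` on the validation patients),
#'   `scores` (named validation scores), `model` (the xgboost handle).
#' @export
fitEvaluate <- function(table_train, table_val, seed = 1, nrounds = 200,
                        max_depth = 3, eta = 0.1) {
  feat_cols <- setdiff(names(table_train), c("patient_id", "label"))
  if (!identical(feat_cols,
                 setdiff(names(table_val), c("patient_id", "label")))) {
    extra <- union(setdiff(names(table_val), names(table_train)),
                   setdiff(names(table_train), names(table_val)))
    stop(sprintf("feature column mismatch: %s", paste(extra, collapse = ", ")))
  }
  if (length(intersect(table_train$patient_id, table_val$patient_id)))
    stop("train and validation tables share patients")
  y_tr <- labelTo01(table_train$label)
  y_va <- labelTo01(table_val$label)
  if (length(unique(y_tr)) < 2)
    stop("training labels contain a single class")
  X_tr <- as.matrix(table_train[, feat_cols, drop = FALSE])
  X_va <- as.matrix(table_val[, feat_cols, drop = FALSE])
  set.seed(seed)
  dtr <- xgboost::xgb.DMatrix(X_tr, label = y_tr)
  dva <- xgboost::xgb.DMatrix(X_va, label = y_va)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = seed),
    data = dtr, nrounds = nrounds,
    evals = list(val = dva),
    early_stopping_rounds = 20, verbose = 0)
  scores <- predict(fit, dva)
  names(scores) <- table_val$patient_id
  list(report = classificationReport(scores, y_va), scores = scores,
       model = fit)
}
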