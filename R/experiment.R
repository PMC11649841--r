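#' End-to-end single-cohort experiment
#'
#' Runs the full modelling stage on a cohort of minute panels: extracts
#' WTLCC matrices for one signal pair, trains the CNN on the training
#' patients of a patient-grouped split, scores the held-out patients with
#' mean-score aggregation, and (optionally) fits the gradient-boosted
#' comparison models on averaged indices and on CNN embeddings, both
#' adjusted for the CRASH covariates and reusing the same patient
#' partition.
#'
#' @param cohort list with `panels` (named [MinutePanel-class] list) and
#'   `records` (metadata data.frame).
#' @param pair character vector of two index names.
#' @param params a [wtlccParams()].
#' @param config a [cnnConfig()].
#' @param split patient-grouped split from [patientSplit()].
#' @param tabular also fit the averages/embeddings XGBoost comparison.
#' @param outcome outcome column used as label.
#' @return list: `scorer`, `patient_scores` (held-out), `report`
#'   (`EvalReport`), `matrices_by_patient`, and when `tabular` is `TRUE`,
#'   `tabular_averages` and `tabular_embeddings` reports.
#' @export
runWTLCCExperiment <- function(cohort, pair = c("icp", "lfhf"),
                               params = wtlccParams(), config = cnnConfig(),
                               split, tabular = FALSE,
                               outcome = "outcome_short") {
  labels <- setNames(cohort$records[[outcome]], cohort$records$patient_id)
  mbp <- lapply(cohort$panels, extractMatrices, pair = pair, params = params)
  ev <- fitAndScore(mbp, labels, config, split)
  report <- classificationReport(ev$scores, labels[names(ev$scores)])
  out <- list(scorer = ev$scorer, patient_scores = ev$scores,
              report = report, matrices_by_patient = mbp, split = split)
  if (tabular) {
    rec_tr <- cohort$records[cohort$records$patient_id %in% split$train, ]
    rec_va <- cohort$records[cohort$records$patient_id %in% split$val, ]
    avg_tr <- buildFeatures(rec_tr, panels = cohort$panels,
                            mode = "averages", outcome = outcome)
    avg_va <- buildFeatures(rec_va, panels = cohort$panels,
                            mode = "averages", outcome = outcome)
    emb_tr <- buildFeatures(rec_tr, mode = "embeddings", scorer = ev$scorer,
                            matrices_by_patient = mbp, outcome = outcome)
    emb_va <- buildFeatures(rec_va, mode = "embeddings", scorer = ev$scorer,
                            matrices_by_patient = mbp, outcome = outcome)
    out$tabular_averages <- fitEvaluate(avg_tr, avg_va,
                                        seed = config$seed)$report
    out$tabular_embeddings <- fitEvaluate(emb_tr, emb_va,
                                          seed = config$seed)$report
  }
  out
}

#' Run a configured experiment into a run directory
#'
#' Orchestrates simulate -> (derive) -> wtlcc -> train -> evaluate ->
#' compare from a single configuration (an R list or a YAML file path),
#' persisting the configuration, per-patient panels, metrics and a manifest
#' with seeds and per-stage output checksums into a run directory with the
#' fixed layout `config.yaml`, `panels/`, `reports/`.
#'
#' Two designs are supported: `"single_cohort"` (one simulated cohort,
#' patient-grouped train/validation split) and `"two_cohort"` (a training
#' cohort and a separate validation cohort that share no patient, mirroring
#' external validation; the two cohorts are never mixed).
#'
#' @param config list or YAML path.  Recognized fields: `design`
#'   (`"single_cohort"`/`"two_cohort"`), `n_patients`, `duration_h`,
#'   `seed`, `val_frac`, `pair`, `wtlcc` (list N/S/K/J, plus `paper_mode`),
#'   `cnn` (passed to [cnnConfig()]), `class_params` overrides, `tabular`
#'   (logical).
#' @param out_dir run directory (created; must not already contain a
#'   manifest).
#' @return list with `metrics`, `manifest`, and the run directory path.
#' @export
runExperiment <- function(config, out_dir = tempfile("wtlcc_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(list(design = "single_cohort", n_patients = 12,
                         duration_h = 24, seed = 1, val_frac = 0.3,
                         pair = c("icp", "lfhf"),
                         wtlcc = list(N = 360, S = 90, K = 30, J = 240),
                         cnn = list(), tabular = FALSE), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.exists(file.path(out_dir, "manifest.json")))
    stop("run directory already contains a manifest")
  dir.create(file.path(out_dir, "panels"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "reports"), showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  params <- do.call(wtlccParams, cfg$wtlcc)
  cnn_cfg <- do.call(cnnConfig, c(cfg$cnn, list(seed = cfg$seed)))
  make_cohort <- function(n, seed, tag) {
    spec <- simCohortSpec(n_patients = n, duration_h = cfg$duration_h,
                          seed = seed)
    if (!is.null(cfg$class_params))
      spec$class_params <- cfg$class_params
    co <- simulateCohort(spec)
    co$records$patient_id <- paste0(tag, co$records$patient_id)
    names(co$panels) <- co$records$patient_id
    for (pid in names(co$panels)) {
      co$panels[[pid]]@patient_id <- pid
      writePanelCSV(co$panels[[pid]],
                    file.path(out_dir, "panels", paste0(pid, ".csv")))
    }
    writeMetadataCSV(co$records,
                     file.path(out_dir, paste0("metadata_", tag, "csv")))
    co
  }
  if (cfg$design == "single_cohort") {
    cohort <- make_cohort(cfg$n_patients, cfg$seed, "A")
    labels <- setNames(cohort$records$outcome_short,
                       cohort$records$patient_id)
    split <- patientSplit(labels, val_frac = cfg$val_frac,
                          seed = cfg$seed)
  } else if (cfg$design == "two_cohort") {
    co_a <- make_cohort(cfg$n_patients, cfg$seed, "A")
    co_b <- make_cohort(cfg$n_patients, cfg$seed + 1, "B")
    if (length(intersect(co_a$records$patient_id, co_b$records$patient_id)))
      stop("training and validation cohorts share patient ids")
    cohort <- list(panels = c(co_a$panels, co_b$panels),
                   records = rbind(co_a$records, co_b$records))
    split <- list(train = co_a$records$patient_id,
                  val = co_b$records$patient_id)
  } else stop("unknown design")
  res <- runWTLCCExperiment(cohort, pair = cfg$pair, params = params,
                            config = cnn_cfg, split = split,
                            tabular = isTRUE(cfg$tabular))
  metrics <- list(auc = res$report$auc, accuracy = res$report$accuracy,
                  f1 = res$report$f1,
                  n_val_patients = res$report$n_patients)
  if (isTRUE(cfg$tabular)) {
    metrics$tabular_averages_auc <- res$tabular_averages$auc
    metrics$tabular_embeddings_auc <- res$tabular_embeddings$auc
  }
  jsonlite::write_json(metrics, file.path(out_dir, "reports", "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  panel_files <- sort(list.files(file.path(out_dir, "panels"),
                                 full.names = TRUE))
  manifest <- list(
    design = cfg$design, seed = cfg$seed,
    n_patients = length(cohort$panels),
    split = split,
    stage_checksums = list(
      panels = unname(vapply(panel_files, function(f)
        as.character(tools::md5sum(f)), character(1))),
      metrics = as.character(tools::md5sum(
        file.path(out_dir, "reports", "metrics.json")))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(metrics = metrics, manifest = manifest, dir = out_dir,
       result = res)
}
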