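#' Hyperparameter search space
#'
#' Discrete space over signal pairs and WTLCC geometry.  Defaults cover all
#' six hemodynamic-autonomic pairings; in paper mode the geometry grids are
#' the published sets with `J` fixed at 240.
#'
#' @param pairs list of 2-vectors of index names (first = I1, second = I2).
#' @param N_set,S_set,K_set candidate WTLCC grids, min.
#' @param J lag-column count (fixed across the space).
#' @param budget number of trials.
#' @return list of class `SearchSpace`.
#' @export
searchSpace <- function(pairs = list(c("icp", "lfhf"), c("icp", "brs"),
                                     c("cpp", "lfhf"), c("cpp", "brs"),
                                     c("prx", "lfhf"), c("prx", "brs")),
                        N_set = c(360, 720, 1080), S_set = c(15, 30, 60, 90),
                        K_set = c(15, 30, 60), J = 240, budget = 20) {
  if (!length(pairs) || !length(N_set) || !length(S_set) || !length(K_set))
    stop("search space dimensions must be non-empty")
  if (budget < 1) stop("budget must be >= 1")
  structure(list(pairs = pairs, N_set = N_set, S_set = S_set,
                 K_set = K_set, J = J, budget = budget),
            class = "SearchSpace")
}

# Laplace-smoothed categorical probability of `value` among `obs` drawn from
# `levels`
catProb <- function(value, obs, levels) {
  (sum(obs == value) + 1) / (length(obs) + length(levels))
}

# sample one element of x (guarding the length-1 sample() surprise)
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Sequential model-based search over WTLCC geometry and signal pairs
#'
#' Tree-structured-Parzen-estimator style optimization over the discrete
#' space: an initial design stratified across the signal pairs (each pair is
#' tried once, with random geometry, before any pair is repeated), then
#' candidates sampled and ranked by the ratio of smoothed categorical
#' densities fitted to the good (top quartile) versus remaining trials.  The
#' objective is patient-level validation AUC, with validation log-loss as
#' tie-break.  Reproducible given `seed`.
#'
#' @param cohort a [simulateCohort()] result (minute fidelity) or a list
#'   with `panels` and `records`.
#' @param space a [searchSpace()].
#' @param split patient-grouped split from [patientSplit()].
#' @param config_base a [cnnConfig()] whose architecture/optimizer settings
#'   are reused for every trial.
#' @param seed integer seed.
#' @param outcome outcome column used as label.
#' @return list: `best` (pair, params, config, objective), `trials`
#'   (data.frame log).
#' @export
searchHyperparameters <- function(cohort, space, split,
                                  config_base = cnnConfig(), seed = 1,
                                  outcome = "outcome_short") {
  stopifnot(inherits(space, "SearchSpace"))
  set.seed(seed)
  labels <- setNames(cohort$records[[outcome]], cohort$records$patient_id)
  pair_key <- vapply(space$pairs, paste, character(1), collapse = ":")
  n_pairs <- length(space$pairs)
  cache <- new.env(parent = emptyenv())
  trial_seeds <- sample.int(.Machine$integer.max - 1L, space$budget)
  startup_pairs <- sample(seq_len(n_pairs))
  log <- data.frame()
  results <- list()
  errors <- character()
  for (t in seq_len(space$budget)) {
    if (t <= n_pairs || nrow(log) == 0) {
      ip <- if (t <= n_pairs) startup_pairs[t]
            else sample1(seq_len(n_pairs))
      N <- sample1(space$N_set); S <- sample1(space$S_set)
      K <- sample1(space$K_set)
    } else {
      obj <- log$objective
      ord <- order(-obj, log$val_loss)
      n_good <- max(1L, ceiling(0.25 * nrow(log)))
      good <- log[ord[seq_len(n_good)], ]
      bad <- log[ord[-seq_len(n_good)], ]
      best_score <- -Inf
      for (cand in seq_len(24)) {
        cip <- sample1(seq_len(n_pairs))
        cN <- sample1(space$N_set); cS <- sample1(space$S_set)
        cK <- sample1(space$K_set)
        l <- catProb(pair_key[cip], good$pair, pair_key) *
          catProb(cN, good$N, space$N_set) *
          catProb(cS, good$S, space$S_set) *
          catProb(cK, good$K, space$K_set)
        g <- catProb(pair_key[cip], bad$pair, pair_key) *
          catProb(cN, bad$N, space$N_set) *
          catProb(cS, bad$S, space$S_set) *
          catProb(cK, bad$K, space$K_set)
        if (l / g > best_score) {
          best_score <- l / g
          ip <- cip; N <- cN; S <- cS; K <- cK
        }
      }
    }
    if (N %% K != 0) {
      ks <- space$K_set[N %% space$K_set == 0 & space$K_set <= N]
      if (length(ks)) K <- max(ks)
    }
    res <- tryCatch({
      params <- wtlccParams(N = N, S = S, K = K, J = space$J)
      key <- paste(pair_key[ip], N, S, K, sep = "|")
      if (is.null(cache[[key]]))
        cache[[key]] <- lapply(cohort$panels, extractMatrices,
                               pair = space$pairs[[ip]], params = params)
      mbp <- cache[[key]]
      cfg <- config_base
      cfg$seed <- trial_seeds[t]
      ev <- fitAndScore(mbp, labels, cfg, split)
      list(objective = ev$auc, val_loss = ev$val_loss, params = params,
           config = cfg, scorer = ev$scorer)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("trial %d (%s N=%d S=%d K=%d): %s",
                                  t, pair_key[ip], N, S, K,
                                  conditionMessage(res)))
      next
    }
    log <- rbind(log, data.frame(
      trial = t, pair = pair_key[ip], N = N, S = S, K = K,
      objective = res$objective, val_loss = res$val_loss))
    results[[length(results) + 1L]] <- res
  }
  if (!nrow(log))
    stop(paste(c("all trials failed:", errors), collapse = "\n  "))
  ord <- order(-log$objective, log$val_loss)
  best_i <- ord[1]
  best <- results[[best_i]]
  list(best = list(pair = strsplit(log$pair[best_i], ":")[[1]],
                   params = best$params, config = best$config,
                   objective = best$objective, scorer = best$scorer),
       trials = log, errors = errors)
}

# train on the split's training patients, score validation patients;
# returns patient-level AUC, final validation loss and the scorer
fitAndScore <- function(matrices_by_patient, labels, config, split) {
  train_m <- unlist(matrices_by_patient[split$train], recursive = FALSE)
  val_m <- unlist(matrices_by_patient[split$val], recursive = FALSE)
  if (length(train_m) == 0 || length(val_m) == 0)
    stop("a split side has no matrices")
  scorer <- trainScorer(c(train_m, val_m), labels, config,
                        val_patients = split$val)
  val_ids <- intersect(split$val, names(matrices_by_patient))
  val_ids <- val_ids[vapply(matrices_by_patient[val_ids], length,
                            integer(1)) > 0]
  scores <- vapply(val_ids, function(pid)
    scorePatient(scorer, matrices_by_patient[[pid]])$score, numeric(1))
  auc <- aucRank(scores, labels[val_ids])
  list(auc = auc, val_loss = tail(scorer@history$val_loss, 1),
       scorer = scorer, scores = scores)
}
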