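#' Dichotomize outcome scale values
#'
#' GOS (1-5): favourable for 4-5, unfavourable for 1-3.  GOS-E (1-8):
#' favourable for 5-8, unfavourable for 4 or less.
#'
#' @param scale `"GOS"` or `"GOSE"`.
#' @param value integer vector of scale values.
#' @return character vector of `"fav"`/`"unfav"`.
#' @export
dichotomize <- function(scale = c("GOS", "GOSE"), value) {
  scale <- match.arg(scale)
  value <- as.integer(value)
  rng <- if (scale == "GOS") c(1L, 5L) else c(1L, 8L)
  if (any(is.na(value)) || any(value < rng[1] | value > rng[2]))
    stop(sprintf("%s values must lie in %d-%d", scale, rng[1], rng[2]))
  cut_fav <- if (scale == "GOS") 4L else 5L
  ifelse(value >= cut_fav, "fav", "unfav")
}

#' AUC by the rank statistic
#'
#' Mann-Whitney formulation with ties averaged: the probability that a
#' randomly chosen positive (unfavourable) scores above a randomly chosen
#' negative, counting ties as one half.
#'
#' @param scores numeric scores (higher = more unfavourable).
#' @param labels outcome labels (`"fav"`/`"unfav"` or 0/1 with 1 =
#'   unfavourable).
#' @return AUC in `[0, 1]`; `NA` if only one class is present.
#' @export
aucRank <- function(scores, labels) {
  y <- labelTo01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification report
#'
#' AUC (rank statistic, ties averaged), accuracy, F1 for the positive =
#' unfavourable class, and the 2x2 confusion matrix (rows = true class,
#' columns = predicted) at the given threshold, applied strictly (predicted
#' unfavourable iff score > threshold).
#'
#' @param scores per-patient scores in `[0, 1]`.
#' @param labels per-patient outcome labels.
#' @param threshold decision threshold (default 0.5).
#' @return list of class `EvalReport`: `auc`, `accuracy`, `f1`, `confusion`,
#'   `n_patients`, `threshold`.
#' @export
classificationReport <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0) stop("empty input")
  if (length(scores) != length(labels))
    stop("scores and labels lengths differ")
  y <- labelTo01(labels)
  pred <- as.numeric(scores > threshold)
  conf <- matrix(0L, 2, 2,
                 dimnames = list(true = c("fav", "unfav"),
                                 pred = c("fav", "unfav")))
  for (i in seq_along(y))
    conf[y[i] + 1L, pred[i] + 1L] <- conf[y[i] + 1L, pred[i] + 1L] + 1L
  tp <- conf[2, 2]; fp <- conf[1, 2]; fn <- conf[2, 1]
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  auc <- aucRank(scores, y)
  if (is.na(auc))
    warning("AUC undefined: labels contain a single class")
  structure(list(auc = auc, accuracy = sum(diag(conf)) / sum(conf),
                 f1 = f1, confusion = conf, n_patients = length(y),
                 threshold = threshold),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport: n = %d, AUC = %.3f, accuracy = %.3f, F1 = %.3f\n",
              x$n_patients, x$auc, x$accuracy, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Cohort comparison statistics
#'
#' Compares per-patient variables between outcome classes: continuous
#' variables by two-sided Mann-Whitney U (exact when both groups have at
#' most 8 patients and no ties, asymptotic otherwise), reported as median
#' (Q1-Q3) per class with Shapiro-Wilk normality p-values recorded;
#' categorical variables by Pearson chi-squared, falling back to Fisher's
#' exact test when any expected cell count is 5 or less.
#'
#' @param features data.frame of per-patient variables (numeric columns are
#'   treated as continuous, others as categorical).
#' @param labels per-patient outcome labels (`"fav"`/`"unfav"`).
#' @param exact_max largest per-group n for which the exact Mann-Whitney
#'   distribution is requested.
#' @return data.frame with one row per variable: class summaries, test used
#'   and p-value.
#' @export
cohortCompare <- function(features, labels, exact_max = 8) {
  y <- labelTo01(labels)
  if (sum(y == 0) < 2 || sum(y == 1) < 2)
    stop("need at least 2 patients per class")
  fmt <- function(v) sprintf("%.2f (%.2f-%.2f)", median(v, na.rm = TRUE),
                             quantile(v, 0.25, na.rm = TRUE),
                             quantile(v, 0.75, na.rm = TRUE))
  rows <- lapply(names(features), function(nm) {
    v <- features[[nm]]
    if (is.numeric(v)) {
      g0 <- v[y == 0]; g1 <- v[y == 1]
      sw <- tryCatch(shapiro.test(v)$p.value, error = function(e) NA_real_)
      exact <- max(sum(!is.na(g0)), sum(!is.na(g1))) <= exact_max
      p <- suppressWarnings(
        wilcox.test(g0, g1, exact = exact, correct = !exact)$p.value)
      data.frame(variable = nm, type = "continuous",
                 favourable = fmt(g0), unfavourable = fmt(g1),
                 test = if (exact) "Mann-Whitney (exact)"
                        else "Mann-Whitney", p_value = p,
                 shapiro_p = sw, stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(v), factor(y, levels = c(0, 1)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected <= 5)) {
        p <- fisher.test(tab)$p.value
        test <- "Fisher exact"
      } else {
        p <- chisq.test(tab, correct = FALSE)$p.value
        test <- "Chi-squared"
      }
      cnt <- function(cl) paste(sprintf("%s: %d", rownames(tab),
                                        tab[, cl]), collapse = "; ")
      data.frame(variable = nm, type = "categorical",
                 favourable = cnt("0"), unfavourable = cnt("1"),
                 test = test, p_value = p, shapiro_p = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
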