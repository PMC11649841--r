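#' Render a WTLCC matrix as a heatmap
#'
#' Lag (minutes) on the x axis, sub-window index on the y axis, correlation
#' on a blue-white-red scale over `[-1, 1]`; missing entries are left blank.
#'
#' @param m a [WTLCCMatrix-class].
#' @param file PNG path; `NULL` draws on the current device.
#' @export
plotMatrix <- function(m, file = NULL) {
  stopifnot(is(m, "WTLCCMatrix"))
  v <- matrixValues(m)
  J <- ncol(v)
  lags <- columnLag(seq_len(J) - 1, J)
  if (!is.null(file)) grDevices::png(file, width = 900, height = 400)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  graphics::image(x = lags, y = seq_len(nrow(v)), z = t(v)[, , drop = FALSE],
                  zlim = c(-1, 1), col = pal,
                  xlab = "lag [min]", ylab = "window index",
                  main = sprintf("%s ~ %s (patient %s, start %d min)",
                                 m@pair[1], m@pair[2], m@patient_id,
                                 as.integer(m@window_start)))
  graphics::abline(v = 0, lty = 2)
  if (!is.null(file)) grDevices::dev.off()
  invisible(m)
}

#' Plot the ROC curve for patient scores
#'
#' @param scores per-patient scores.
#' @param labels per-patient outcome labels (`"fav"`/`"unfav"`).
#' @param file PNG path; `NULL` draws on the current device.
#' @export
plotROC <- function(scores, labels, file = NULL) {
  y <- labelTo01(labels)
  thr <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[y == 1] > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[y == 0] > t), numeric(1))
  if (!is.null(file)) grDevices::png(file, width = 500, height = 500)
  graphics::plot(fpr, tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("ROC (AUC = %.2f)", aucRank(scores, y)))
  graphics::abline(0, 1, lty = 3)
  if (!is.null(file)) grDevices::dev.off()
  invisible(NULL)
}

#' Plot a confusion matrix
#'
#' @param report an `EvalReport` from [classificationReport()].
#' @param file PNG path; `NULL` draws on the current device.
#' @export
plotConfusion <- function(report, file = NULL) {
  conf <- report$confusion
  if (!is.null(file)) grDevices::png(file, width = 450, height = 450)
  graphics::image(1:2, 1:2, t(conf)[, 2:1], col = grDevices::hcl.colors(
    25, "Blues", rev = TRUE), axes = FALSE,
    xlab = "predicted", ylab = "true",
    main = sprintf("accuracy %.2f, F1 %.2f", report$accuracy, report$f1))
  graphics::axis(1, at = 1:2, labels = colnames(conf))
  graphics::axis(2, at = 1:2, labels = rev(rownames(conf)))
  for (i in 1:2) for (j in 1:2)
    graphics::text(j, 3 - i, conf[i, j], cex = 2)
  if (!is.null(file)) grDevices::dev.off()
  invisible(NULL)
}
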