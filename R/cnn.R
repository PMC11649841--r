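#' CNN training configuration
#'
#' Default architecture: three conv blocks of 16/32/64 filters with 3x3
#' kernels and 2x2 max pooling, the final feature map flattened into a dense
#' embedding of width 64 (flattening, not global pooling, because the lag
#' *position* of correlation ridges is the discriminative feature), dropout
#' 0.25 and a sigmoid head — the smallest family that resolves the lag
#' structure of 60 x 240 matrices on a CPU.  Scores are P(unfavourable
#' outcome).
#'
#' @param conv_blocks list of conv blocks, each `list(filters, kernel,
#'   pool)`.
#' @param dense_width width of the dense embedding layer.
#' @param dropout dropout probability on the embedding during training.
#' @param learning_rate Adam learning rate.
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param class_weighting `"balanced"` (inverse class frequency) or
#'   `"none"`.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return A validated list of class `CNNConfig`.
#' @export
cnnConfig <- function(conv_blocks = list(list(filters = 16, kernel = 3, pool = 2),
                                         list(filters = 32, kernel = 3, pool = 2),
                                         list(filters = 64, kernel = 3, pool = 2)),
                      dense_width = 64, dropout = 0.25,
                      learning_rate = 1e-3, batch_size = 32, epochs = 30,
                      class_weighting = c("balanced", "none"), seed = 1) {
  class_weighting <- match.arg(class_weighting)
  if (length(conv_blocks) < 1) stop("need at least one conv block")
  kernels <- vapply(conv_blocks, `[[`, numeric(1), "kernel")
  pools <- vapply(conv_blocks, `[[`, numeric(1), "pool")
  if (length(unique(kernels)) != 1L || length(unique(pools)) != 1L)
    stop("all conv blocks must share kernel and pool size")
  if (kernels[1] %% 2 != 1) stop("kernel size must be odd")
  structure(list(conv_blocks = conv_blocks, dense_width = dense_width,
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = batch_size, epochs = epochs,
                 class_weighting = class_weighting, seed = seed),
            class = "CNNConfig")
}

# outcome labels ("fav"/"unfav") -> numeric 0/1 with unfavourable = 1
labelTo01 <- function(labels) {
  if (is.numeric(labels)) return(as.numeric(labels))
  lv <- tolower(as.character(labels))
  if (!all(lv %in% c("fav", "unfav", "favourable", "unfavourable")))
    stop("labels must be 'fav'/'unfav'")
  as.numeric(lv %in% c("unfav", "unfavourable"))
}

# stack WTLCC matrices into a K x J x n cube; missing entries are imputed as
# 0 here, at the model-input boundary only
stackMatrices <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  K <- nrow(matrices[[1]]@values); J <- ncol(matrices[[1]]@values)
  X <- array(0, dim = c(K, J, length(matrices)))
  for (i in seq_along(matrices)) {
    v <- matrices[[i]]@values
    if (nrow(v) != K || ncol(v) != J) stop("matrix shape mismatch")
    v[is.na(v)] <- 0
    X[, , i] <- v
  }
  X
}

#' Patient-grouped train/validation split
#'
#' Splits *patient identifiers* (never individual matrices) into training and
#' validation groups, stratified by outcome class so both classes appear on
#' both sides.
#'
#' @param labels named vector of per-patient outcome labels
#'   (`"fav"`/`"unfav"`); names are patient ids.
#' @param val_frac fraction of patients per class held out for validation.
#' @param seed integer seed.
#' @return list with character vectors `train` and `val`.
#' @export
patientSplit <- function(labels, val_frac = 0.25, seed = 1) {
  stopifnot(!is.null(names(labels)))
  set.seed(seed)
  y <- labelTo01(labels)
  ids <- names(labels)
  val <- character()
  for (cls in unique(y)) {
    cls_ids <- sample(ids[y == cls])
    n_val <- max(1L, round(val_frac * length(cls_ids)))
    val <- c(val, cls_ids[seq_len(n_val)])
  }
  list(train = setdiff(ids, val), val = val)
}

#' Train the convolutional outcome scorer
#'
#' Fits the CNN on WTLCC matrices with per-patient outcome labels,
#' minimizing (optionally class-balanced) binary cross-entropy with Adam.
#' The training/validation split is by patient: matrices from
#' `val_patients` are never seen during weight updates and are only used for
#' the per-epoch validation loss.  Deterministic given `config$seed`.
#'
#' @param matrices list of [WTLCCMatrix-class] (all shapes equal).
#' @param labels named per-patient outcome vector (`"fav"`/`"unfav"`).
#' @param config a [cnnConfig()].
#' @param val_patients optional character vector of patient ids held out for
#'   validation monitoring.
#' @return A [TrainedScorer-class].
#' @export
trainScorer <- function(matrices, labels, config = cnnConfig(),
                        val_patients = NULL) {
  stopifnot(inherits(config, "CNNConfig"), length(matrices) >= 2)
  pids <- vapply(matrices, matrixPatient, character(1))
  if (!all(pids %in% names(labels)))
    stop("every matrix's patient must have a label")
  y_all <- setNames(labelTo01(labels), names(labels))[pids]
  in_val <- pids %in% val_patients
  y <- y_all[!in_val]
  if (length(unique(y)) < 2)
    stop("training labels contain a single class")
  X <- stackMatrices(matrices[!in_val])
  wts <- rep(1, length(y))
  if (config$class_weighting == "balanced") {
    tab <- table(y)
    wts <- as.numeric(length(y) / (2 * tab[as.character(y)]))
  }
  has_val <- any(in_val)
  if (has_val) {
    Xv <- stackMatrices(matrices[in_val])
    yv <- y_all[in_val]
  } else {
    Xv <- array(0, dim = c(dim(X)[1], dim(X)[2], 1))
    yv <- 0
  }
  filters <- vapply(config$conv_blocks, `[[`, numeric(1), "filters")
  kernel <- config$conv_blocks[[1]]$kernel
  pool <- config$conv_blocks[[1]]$pool
  set.seed(config$seed)
  fit <- cnn_train_cpp(X, y, wts, as.integer(filters), as.integer(kernel),
                       as.integer(pool), as.integer(config$dense_width),
                       config$dropout, config$learning_rate,
                       as.integer(config$batch_size),
                       as.integer(config$epochs), Xv, yv, has_val)
  hist <- data.frame(epoch = seq_along(fit$train_loss),
                     train_loss = fit$train_loss,
                     val_loss = fit$val_loss)
  new("TrainedScorer", weights = fit$weights, config = unclass(config),
      input_shape = dim(X)[1:2], embedding_dim = config$dense_width,
      history = hist)
}

#' Score WTLCC matrices with a fitted scorer
#'
#' @param model a [TrainedScorer-class].
#' @param matrices list of [WTLCCMatrix-class].
#' @return numeric vector of per-matrix scores in `[0, 1]`.
#' @export
scoreMatrices <- function(model, matrices) {
  stopifnot(is(model, "TrainedScorer"))
  if (length(matrices) == 0) stop("patient has no matrices")
  X <- stackMatrices(matrices)
  if (!all(dim(X)[1:2] == model@input_shape))
    stop("matrix shape mismatch with the fitted model")
  as.numeric(cnn_forward_cpp(model@weights, X)$scores)
}

#' Patient-level score and label
#'
#' The patient score is the mean of the scores of all the patient's
#' matrices; the patient is labelled unfavourable iff the mean score
#' strictly exceeds 0.5.
#'
#' @inheritParams scoreMatrices
#' @return list with `score` in `[0, 1]` and `label`
#'   (`"fav"`/`"unfav"`).
#' @export
scorePatient <- function(model, matrices) {
  s <- scoreMatrices(model, matrices)
  sc <- mean(s)
  list(score = sc, label = if (sc > 0.5) "unfav" else "fav")
}

#' Patient-level embedding
#'
#' Per-matrix embeddings are read from the penultimate (dense) layer and
#' averaged over the patient's matrices into one fixed-length vector.
#'
#' @inheritParams scoreMatrices
#' @return numeric vector of length `embedding_dim`.
#' @export
embedPatient <- function(model, matrices) {
  stopifnot(is(model, "TrainedScorer"))
  if (length(matrices) == 0) stop("patient has no matrices")
  X <- stackMatrices(matrices)
  if (!all(dim(X)[1:2] == model@input_shape))
    stop("matrix shape mismatch with the fitted model")
  emb <- cnn_forward_cpp(model@weights, X)$embeddings
  colMeans(emb)
}
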