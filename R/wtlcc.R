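#' WTLCC geometry parameters
#'
#' Geometry of a windowed time-lagged cross-correlation matrix: an analysis
#' window of `N` minutes split into `K` contiguous non-overlapping
#' sub-windows of `N/K` minutes (rows), correlated at `J` lags of
#' `j - J/2` minutes (columns, `j = 0..J-1`), with successive analysis
#' windows placed every `S` minutes.
#'
#' In paper mode the grids are restricted to the published sets
#' `N` in \{360, 720, 1080\} min, `S` in \{15, 30, 60, 90\} min,
#' `K` in \{15, 30, 60\} and `J = 240`.
#'
#' @param N analysis-window span, min.
#' @param S stride between successive matrices, min.
#' @param K number of sub-windows (rows); must divide `N`.
#' @param J number of lag columns (even); default 240 (lags from -120 to
#'   +119 min at 1-min resolution).
#' @param min_valid_frac minimum fraction of valid pairs for an entry to be
#'   computed (default 0.8); guards edge columns and gappy data.
#' @param paper_mode restrict `N`, `S`, `K`, `J` to the published sets.
#' @return A validated list of class `WTLCCParams`.
#' @export
wtlccParams <- function(N = 1080, S = 90, K = 60, J = 240,
                        min_valid_frac = 0.8, paper_mode = FALSE) {
  if (J %% 2 != 0) stop("J must be even")
  if (S < 1) stop("S must be >= 1 min")
  if (N < K || K < 1) stop("need N >= K >= 1")
  if (N %% K != 0)
    stop("K must divide N (contiguous equal-length sub-windows)")
  if (paper_mode) {
    if (!N %in% c(360, 720, 1080)) stop("paper mode: N must be in {360, 720, 1080}")
    if (!S %in% c(15, 30, 60, 90)) stop("paper mode: S must be in {15, 30, 60, 90}")
    if (!K %in% c(15, 30, 60)) stop("paper mode: K must be in {15, 30, 60}")
    if (J != 240) stop("paper mode: J is fixed at 240")
  }
  structure(list(N = N, S = S, K = K, J = J,
                 min_valid_frac = min_valid_frac, paper_mode = paper_mode),
            class = "WTLCCParams")
}

#' Lag of a matrix column
#'
#' Column `j` (0-based) of a `J`-column WTLCC matrix holds the correlation at
#' lag `j - J/2` minutes.  A positive lag means the second series is
#' evaluated later than the first (the first series leads).
#'
#' @param j 0-based column index, `0 <= j < J`.
#' @param J number of lag columns.
#' @return lag in minutes.
#' @export
columnLag <- function(j, J) {
  if (any(j < 0 | j >= J)) stop("column index out of range [0, J)")
  j - J / 2
}

#' Build one windowed time-lagged cross-correlation matrix
#'
#' Entry `(k, j)` is the Pearson correlation between `I1` restricted to
#' sub-window `k` (minutes `[start + k*w, start + (k+1)*w)`, `w = N/K`) and
#' `I2` shifted by [columnLag()]`(j, J)` minutes.  Lagged samples are drawn
#' from the full series beyond the analysis window when available; pairs
#' falling outside the series are missing (no zero padding).  Entries with
#' fewer than `min_valid_frac * w` valid pairs, or zero variance on either
#' side, are `NA`.
#'
#' @param I1,I2 aligned [MinuteSeries-class] objects (same start and
#'   length).
#' @param start analysis-window start, minutes from onset (absolute).
#' @param params a [wtlccParams()].
#' @param patient_id,pair provenance recorded in the matrix.
#' @return A [WTLCCMatrix-class].
#' @export
buildMatrix <- function(I1, I2, start, params, patient_id = "p1",
                        pair = c("I1", "I2")) {
  stopifnot(is(I1, "MinuteSeries"), is(I2, "MinuteSeries"),
            inherits(params, "WTLCCParams"))
  if (I1@start_min != I2@start_min ||
      length(I1@values) != length(I2@values))
    stop("I1 and I2 must share start and length")
  N <- params$N; K <- params$K; J <- params$J
  w <- N / K
  if (w < 3) stop("sub-window shorter than 3 min (K too large for N)")
  x1 <- seriesValues(I1); x2 <- seriesValues(I2)
  T <- length(x1)
  i0 <- start - I1@start_min           # 0-based offset of window start
  if (i0 < 0 || i0 + N > T)
    stop("analysis window [start, start+N) not covered by the series")
  # centring both series by their grand means leaves every per-window
  # Pearson correlation unchanged and keeps the moment sums well conditioned
  x1 <- x1 - mean(x1, na.rm = TRUE)
  x2 <- x2 - mean(x2, na.rm = TRUE)
  half <- J / 2
  pad <- rep(NA_real_, half)
  x2p <- c(pad, x2, pad)               # index shift: pos p -> x2p[p + half]
  idx <- outer(seq_len(w), (seq_len(K) - 1) * w, "+") + i0   # w x K, 1-based
  A <- matrix(x1[idx], nrow = w)
  vals <- matrix(NA_real_, K, J)
  min_n <- max(3, ceiling(params$min_valid_frac * w))
  eps <- 1e-12
  for (jj in seq_len(J)) {
    l <- columnLag(jj - 1, J)
    B <- matrix(x2p[idx + l + half], nrow = w)
    ok <- is.finite(A) & is.finite(B)
    n <- colSums(ok)
    Am <- A; Bm <- B
    Am[!ok] <- 0; Bm[!ok] <- 0
    sa <- colSums(Am); sb <- colSums(Bm)
    ma <- sa / n; mb <- sb / n
    va <- colSums(Am^2) - n * ma^2
    vb <- colSums(Bm^2) - n * mb^2
    cv <- colSums(Am * Bm) - n * ma * mb
    r <- cv / sqrt(va * vb)
    r[n < min_n | va <= eps | vb <= eps] <- NA_real_
    vals[, jj] <- pmin(1, pmax(-1, r))
  }
  new("WTLCCMatrix", values = vals, patient_id = patient_id,
      window_start = start, params = unclass(params), pair = pair)
}

#' Extract all WTLCC matrices from a panel
#'
#' Slides the `N`-minute analysis window over the panel with stride `S`
#' (starts at 0, S, 2S, ...), building one matrix per placement; for a
#' gap-free panel of length `T` this yields `floor((T - N)/S) + 1` matrices.
#' Matrices whose fraction of missing entries exceeds `max_missing_entries`
#' are dropped, with the reason recorded in the `dropped` attribute.
#'
#' @param panel a [MinutePanel-class].
#' @param pair character vector of two index names, e.g. `c("icp", "lfhf")`.
#' @param params a [wtlccParams()].
#' @param max_missing_entries quality filter on the per-matrix fraction of
#'   missing entries (default 0.5).
#' @return list of [WTLCCMatrix-class]; empty (with a warning) if the panel
#'   is shorter than `N`.
#' @export
extractMatrices <- function(panel, pair, params, max_missing_entries = 0.5) {
  stopifnot(is(panel, "MinutePanel"), length(pair) == 2)
  I1 <- panelSeries(panel, pair[1]); I2 <- panelSeries(panel, pair[2])
  T <- panel@length_min
  if (T < params$N) {
    warning(sprintf("panel '%s' shorter (%d min) than N = %d: no matrices",
                    panel@patient_id, T, params$N))
    return(list())
  }
  starts <- seq(I1@start_min, I1@start_min + T - params$N, by = params$S)
  out <- vector("list", length(starts))
  dropped <- character()
  kept <- logical(length(starts))
  for (i in seq_along(starts)) {
    m <- buildMatrix(I1, I2, starts[i], params,
                     patient_id = panel@patient_id, pair = pair)
    frac_na <- mean(is.na(m@values))
    if (frac_na > max_missing_entries) {
      dropped <- c(dropped, sprintf(
        "start %d: %.0f%% entries missing", starts[i], 100 * frac_na))
      next
    }
    out[[i]] <- m
    kept[i] <- TRUE
  }
  out <- out[kept]
  attr(out, "dropped") <- dropped
  out
}
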