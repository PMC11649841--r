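# Small fixtures shared across test files; everything is generated in code.

# gap-free minute series of white noise
randomSeries <- function(n, seed, mean = 0, sd = 1, start_min = 0) {
  set.seed(seed)
  minuteSeries(rnorm(n, mean, sd), start_min = start_min)
}

# naive double-loop WTLCC oracle: explicit slicing + stats::cor, independent
# of the vectorized implementation
naiveWTLCC <- function(x1, x2, start, N, S, K, J, min_valid_frac = 0.8) {
  w <- N / K
  out <- matrix(NA_real_, K, J)
  T <- length(x1)
  for (k in seq_len(K) - 1) {
    i1 <- start + k * w + seq_len(w)       # 1-based window indices
    a <- x1[i1]
    for (j in seq_len(J) - 1) {
      l <- j - J / 2
      i2 <- i1 + l
      ok <- i2 >= 1 & i2 <= T
      b <- rep(NA_real_, w)
      b[ok] <- x2[i2[ok]]
      keep <- !is.na(a) & !is.na(b)
      if (sum(keep) < max(3, ceiling(min_valid_frac * w))) next
      if (sd(a[keep]) == 0 || sd(b[keep]) == 0) next
      out[k + 1, j + 1] <- cor(a[keep], b[keep])
    }
  }
  out
}

# brute-force PRx: explicit 10-s means, explicit Pearson over the 30 most
# recent pairs, mean of the six within-minute updates
brutePRx <- function(abp, icp) {
  m10 <- function(sig) {
    spb <- sig@fs * 10
    nb <- floor(length(sig@samples) / spb)
    vapply(seq_len(nb), function(b)
      mean(sig@samples[(floor((b - 1) * spb) + 1):floor(b * spb)]),
      numeric(1))
  }
  a <- m10(abp); b <- m10(icp)
  nb <- min(length(a), length(b))
  r <- rep(NA_real_, nb)
  for (i in 30:nb)
    r[i] <- cor(a[(i - 29):i], b[(i - 29):i])
  n_min <- floor(nb / 6)
  vapply(seq_len(n_min), function(m)
    mean(r[(6 * (m - 1) + 1):(6 * m)], na.rm = TRUE), numeric(1))
}

# small separable cohort used by CNN / tabular tests: classes differ only in
# the ICP -> LF/HF coupling lag
separableCohort <- function(n_patients = 16, duration_h = 12, seed = 7,
                            lag_fav = 0, lag_unfav = 60, strength = 0.8) {
  spec <- simCohortSpec(
    n_patients = n_patients,
    class_params = list(
      favourable = simPatientParams(coupling_lag = lag_fav,
                                    coupling_strength = strength,
                                    outcome_label = "favourable"),
      unfavourable = simPatientParams(coupling_lag = lag_unfav,
                                      coupling_strength = strength,
                                      outcome_label = "unfavourable")),
    duration_h = duration_h, fidelity = "minute", seed = seed)
  co <- simulateCohort(spec)
  names(co$panels) <- co$records$patient_id
  co
}

tinyCNNConfig <- function(seed = 1, epochs = 8) {
  cnnConfig(conv_blocks = list(list(filters = 4, kernel = 3, pool = 2)),
            dense_width = 8, dropout = 0.1, epochs = epochs,
            batch_size = 16, seed = seed)
}
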