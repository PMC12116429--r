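# Independent brute-force reference implementation of surrogate synchrony.
# Deliberately written with plain scalar loops, explicit vector shifts and
# stats::cor -- it shares no code path with the package internals, so
# agreement is evidence of correctness rather than of shared bugs.

oracle_pair_value <- function(x, y, max_lag, mode, lag_subset, use_fisher_z) {
  n <- length(x)
  vals <- c()
  for (l in -max_lag:max_lag) {
    if (lag_subset == "negative" && l >= 0) next
    if (lag_subset == "positive" && l <= 0) next
    if (l < 0) {
      xs <- x[1:(n + l)]
      ys <- y[(1 - l):n]
    } else if (l > 0) {
      xs <- x[(1 + l):n]
      ys <- y[1:(n - l)]
    } else {
      xs <- x
      ys <- y
    }
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next
    r <- stats::cor(xs, ys)
    r <- max(min(r, 1 - 1e-12), -(1 - 1e-12))
    if (use_fisher_z) r <- atanh(r)
    if (mode == "abs") r <- abs(r)
    vals <- c(vals, r)
  }
  mean(vals)
}

oracle_synchrony <- function(patient, therapist, fs, segment_seconds = 30,
                             max_lag_seconds = 5, use_fisher_z = TRUE) {
  seg_n <- as.integer(round(segment_seconds * fs))
  max_lag <- as.integer(round(max_lag_seconds * fs))
  m <- floor(min(length(patient), length(therapist)) / seg_n)
  psegs <- lapply(seq_len(m), function(i) {
    patient[((i - 1) * seg_n + 1):(i * seg_n)]
  })
  tsegs <- lapply(seq_len(m), function(i) {
    therapist[((i - 1) * seg_n + 1):(i * seg_n)]
  })

  out <- list(n_segments = m)
  variants <- list(
    abs = c("abs", "all"), noabs = c("noabs", "all"),
    abs_pt_lead = c("abs", "negative"), noabs_pt_lead = c("noabs", "negative"),
    abs_th_lead = c("abs", "positive"), noabs_th_lead = c("noabs", "positive")
  )
  for (v in names(variants)) {
    mode <- variants[[v]][1]
    subset <- variants[[v]][2]
    real_vals <- vapply(seq_len(m), function(i) {
      oracle_pair_value(psegs[[i]], tsegs[[i]], max_lag, mode, subset,
                        use_fisher_z)
    }, numeric(1))
    real <- mean(real_vals, na.rm = TRUE)
    # all-pairs scheme: one surrogate session per cyclic rotation k,
    # pairing patient segment i with therapist segment i + k (mod m).
    pseudo <- vapply(seq_len(m - 1), function(k) {
      vals <- vapply(seq_len(m), function(i) {
        j <- ((i - 1 + k) %% m) + 1
        oracle_pair_value(psegs[[i]], tsegs[[j]], max_lag, mode, subset,
                          use_fisher_z)
      }, numeric(1))
      mean(vals, na.rm = TRUE)
    }, numeric(1))
    out[[paste0("real_", v)]] <- real
    out[[paste0("pseudo_mean_", v)]] <- mean(pseudo)
    out[[paste0("pseudo_sd_", v)]] <- stats::sd(pseudo)
    out[[paste0("es_", v)]] <- (real - mean(pseudo)) / stats::sd(pseudo)
  }
  out
}
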