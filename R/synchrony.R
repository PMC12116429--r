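#' Configuration for surrogate synchrony computation
#'
#' Collects the tunable parameters of the surrogate-synchrony analysis.
#' Defaults follow the windowed cross-correlation convention for dyadic
#' physiological series: 30-s segments, lags up to +/- 5 s, Fisher
#' z-transformation of correlations before averaging.
#'
#' @param segment_seconds Segment duration in seconds (default 30).
#' @param max_lag_seconds Maximum cross-correlation lag in seconds
#'   (default 5).
#' @param fisher_z Transform correlations with Fisher's z before
#'   averaging? Default `TRUE`. The statistic then lives consistently on
#'   the z scale for both real and surrogate data; no back-transform is
#'   applied.
#' @param surrogate_scheme `"all-pairs"` (default): deterministic,
#'   exhaustive surrogate sessions formed by the m - 1 cyclic rotations of
#'   the therapist's segments against the patient's, which cover every
#'   ordered mispairing of segments exactly once. `"random-shuffles"`:
#'   `n_shuffles` seeded random permutations of the therapist's segments
#'   with no fixed points.
#' @param n_shuffles Number of random shuffles (random-shuffles scheme
#'   only; default 100).
#' @param seed Integer seed, mandatory for the random-shuffles scheme.
#' @return An object of class `sync_config`.
#' @export
sync_config <- function(segment_seconds = 30, max_lag_seconds = 5,
                        fisher_z = TRUE,
                        surrogate_scheme = c("all-pairs", "random-shuffles"),
                        n_shuffles = 100L, seed = NULL) {
  check_number(segment_seconds, "segment_seconds", lower = 1e-9)
  check_number(max_lag_seconds, "max_lag_seconds", lower = 1e-9)
  check_number(n_shuffles, "n_shuffles", lower = 2)
  surrogate_scheme <- match.arg(surrogate_scheme)
  if (surrogate_scheme == "random-shuffles" && is.null(seed)) {
    stop_dyadsync("The random-shuffles scheme requires a `seed`.",
                  "dyadsync_invalid_parameter")
  }
  structure(
    list(segment_seconds = segment_seconds,
         max_lag_seconds = max_lag_seconds,
         fisher_z = isTRUE(fisher_z),
         surrogate_scheme = surrogate_scheme,
         n_shuffles = as.integer(n_shuffles),
         seed = seed),
    class = "sync_config"
  )
}

# Segment length (samples) and max lag (samples) at a given rate; checks
# the feasibility invariant segment >= 2 * lag + 2.
sync_dims <- function(cfg, fs) {
  seg_n <- as.integer(round(cfg$segment_seconds * fs))
  lag_n <- as.integer(round(cfg$max_lag_seconds * fs))
  if (seg_n < 2L * lag_n + 2L) {
    stop_dyadsync(
      "Segments are too short for the requested maximum lag (need segment length >= 2 * max lag + 2 samples).",
      "dyadsync_invalid_parameter"
    )
  }
  list(seg_n = seg_n, lag_n = lag_n)
}

#' Cut an aligned dyadic session into consecutive segments
#'
#' Both channels are trimmed to their common length and cut into
#' consecutive, non-overlapping segments of `segment_seconds * fs`
#' samples; a trailing partial segment is dropped.
#'
#' @param patient,therapist Numeric vectors of the two phasic EDA series
#'   at rate `fs`.
#' @param fs Sampling rate in Hz (nominally 20).
#' @param segment_seconds Segment duration in seconds (default 30).
#' @return A list with `patient` and `therapist` (each an
#'   `n_per_segment x n_segments` matrix whose columns are segments),
#'   `n_segments`, and `n_dropped` (trailing samples discarded).
#' @export
segment_dyad <- function(patient, therapist, fs, segment_seconds = 30) {
  check_numeric_vector(patient, "patient")
  check_numeric_vector(therapist, "therapist")
  check_number(fs, "fs", lower = 1e-9)
  n <- min(length(patient), length(therapist))
  seg_n <- as.integer(round(segment_seconds * fs))
  m <- n %/% seg_n
  if (m < 2L) {
    stop_dyadsync(
      sprintf("Session too short: %d full %g-s segments (need at least 2 for surrogates).",
              m, segment_seconds),
      "dyadsync_session_too_short"
    )
  }
  used <- m * seg_n
  list(
    patient = matrix(patient[seq_len(used)], nrow = seg_n, ncol = m),
    therapist = matrix(therapist[seq_len(used)], nrow = seg_n, ncol = m),
    n_segments = m,
    n_dropped = n - used
  )
}

# Lagged Pearson correlations between every patient segment and every
# therapist segment, for lags -L..L. Returns an m x m x (2L+1) array;
# element [i, j, l] is the correlation of patient segment i with
# therapist segment j at the l-th lag. Negative lags mean the patient's
# samples precede the therapist's (patient leading). Zero-variance
# overlaps yield NA. Computed per lag as a single cross-product so that
# all m^2 pairings share the work.
lagged_cor_array <- function(psegs, tsegs, lag_n) {
  n <- nrow(psegs)
  m <- ncol(psegs)
  lags <- seq.int(-lag_n, lag_n)
  out <- array(NA_real_, dim = c(m, m, length(lags)))
  for (li in seq_along(lags)) {
    l <- lags[li]
    if (l < 0L) {
      xi <- seq_len(n + l)
      yi <- seq.int(1L - l, n)
    } else if (l > 0L) {
      xi <- seq.int(1L + l, n)
      yi <- seq_len(n - l)
    } else {
      xi <- seq_len(n)
      yi <- xi
    }
    X <- psegs[xi, , drop = FALSE]
    Y <- tsegs[yi, , drop = FALSE]
    Xc <- sweep(X, 2L, colMeans(X))
    Yc <- sweep(Y, 2L, colMeans(Y))
    sx <- sqrt(colSums(Xc^2))
    sy <- sqrt(colSums(Yc^2))
    R <- crossprod(Xc, Yc) / outer(sx, sy)
    R[!is.finite(R)] <- NA_real_
    out[, , li] <- pmin(pmax(R, -1), 1)
  }
  out
}

#' Lagged cross-correlation of one segment pair
#'
#' Pearson correlations between two aligned segments at integer sample
#' lags in `[-max_lag, max_lag]`, each computed over the `N - |lag|`
#' overlapping sample pairs without padding. The sign convention is fixed
#' so that negative lags mean the first (patient) series precedes the
#' second (therapist) series: a peak at lag -3 says the patient's
#' activity is echoed by the therapist 3 samples later.
#'
#' @param x,y Numeric vectors of equal length `N` (patient, therapist).
#' @param max_lag Maximum lag in samples; requires `N > 2 * max_lag + 1`.
#' @return A tibble with columns `lag` and `r`; `r` is `NA` where an
#'   overlap has zero variance.
#' @export
crosscorr_segment <- function(x, y, max_lag) {
  check_numeric_vector(x, "x", min_length = 2L)
  check_numeric_vector(y, "y", min_length = 2L)
  if (length(x) != length(y)) {
    stop_dyadsync("`x` and `y` must have equal length.",
                  "dyadsync_invalid_input")
  }
  check_number(max_lag, "max_lag", lower = 1)
  max_lag <- as.integer(max_lag)
  if (length(x) <= 2L * max_lag + 1L) {
    stop_dyadsync("Segments must be longer than 2 * max_lag + 1 samples.",
                  "dyadsync_invalid_parameter")
  }
  r <- lagged_cor_array(matrix(x, ncol = 1L), matrix(y, ncol = 1L),
                        max_lag)
  tibble(lag = seq.int(-max_lag, max_lag), r = as.numeric(r[1L, 1L, ]))
}

# Logical mask over lags -L..L for a lag subset. Lag 0 belongs to "all"
# only; the leading subsets are strictly one-sided.
lag_subset_mask <- function(lag_n, lag_subset) {
  lags <- seq.int(-lag_n, lag_n)
  switch(lag_subset,
    all = rep(TRUE, length(lags)),
    negative = lags < 0L,
    positive = lags > 0L,
    stop_dyadsync("`lag_subset` must be one of 'all', 'negative', 'positive'.",
                  "dyadsync_invalid_parameter")
  )
}

# Per-pairing session building block: mean over the lag subset of the
# (optionally Fisher-z, optionally absolute) correlations, for every
# (patient segment i, therapist segment j) pairing. Undefined lags are
# dropped from the mean; a pairing with no defined lag is NaN.
segment_pair_values <- function(r_arr, mode, lag_subset, use_fisher_z) {
  lag_n <- (dim(r_arr)[3] - 1L) %/% 2L
  keep <- lag_subset_mask(lag_n, lag_subset)
  z <- r_arr[, , keep, drop = FALSE]
  if (use_fisher_z) z <- fisher_z(z)
  if (mode == "abs") z <- abs(z)
  rowMeans(z, na.rm = TRUE, dims = 2L)
}

#' Aggregate lagged cross-correlations to a session synchrony value
#'
#' Per segment, the correlations over the chosen lag subset are averaged
#' (as absolute values for `mode = "abs"`, signed for `mode = "noabs"`,
#' optionally Fisher-z-transformed first); segment means are then
#' averaged, unweighted, over all segments. Undefined (zero-variance)
#' lags are dropped, never imputed. Lag 0 contributes only to the
#' `"all"` subset; `"negative"` lags are patient-leading and
#' `"positive"` therapist-leading.
#'
#' @param ccf A data frame of per-segment cross-correlations with columns
#'   `segment`, `lag`, `r` (as produced by stacking
#'   [crosscorr_segment()] results).
#' @param mode `"noabs"` (signed, polarity-preserving) or `"abs"`.
#' @param lag_subset `"all"`, `"negative"` (patient-leading) or
#'   `"positive"` (therapist-leading).
#' @param fisher_z Fisher-z-transform correlations before averaging?
#' @return A single synchrony value on the aggregation scale.
#' @export
aggregate_ccf <- function(ccf, mode = c("noabs", "abs"),
                          lag_subset = c("all", "negative", "positive"),
                          fisher_z = TRUE) {
  mode <- match.arg(mode)
  lag_subset <- match.arg(lag_subset)
  if (!is.data.frame(ccf) || !all(c("segment", "lag", "r") %in% names(ccf))) {
    stop_dyadsync("`ccf` needs columns `segment`, `lag`, `r`.",
                  "dyadsync_invalid_input")
  }
  keep <- switch(lag_subset,
    all = rep(TRUE, nrow(ccf)),
    negative = ccf$lag < 0L,
    positive = ccf$lag > 0L
  )
  df <- ccf[keep & !is.na(ccf$r), , drop = FALSE]
  if (nrow(df) == 0L) {
    stop_dyadsync("No defined correlations in the requested lag subset.",
                  "dyadsync_undefined_aggregate")
  }
  v <- df$r
  if (isTRUE(fisher_z)) v <- fisher_z(v)
  if (mode == "abs") v <- abs(v)
  seg_means <- tapply(v, df$segment, mean)
  mean(seg_means)
}

# Surrogate session values from the m x m pairing-value matrix. The
# all-pairs scheme walks the m - 1 cyclic rotations (exhaustive and
# deterministic); the random scheme draws seeded permutations with no
# fixed points. Each surrogate value is a full session aggregate over m
# mispairings, mirroring the real session's aggregate over m true
# pairings.
surrogate_values <- function(v, cfg) {
  m <- nrow(v)
  idx <- seq_len(m)
  if (cfg$surrogate_scheme == "all-pairs") {
    vapply(seq_len(m - 1L), function(k) {
      mean(v[cbind(idx, ((idx - 1L + k) %% m) + 1L)], na.rm = TRUE)
    }, numeric(1))
  } else {
    perms <- withr::with_seed(cfg$seed, {
      lapply(seq_len(cfg$n_shuffles), function(i) {
        repeat {
          p <- sample.int(m)
          if (!any(p == idx)) return(p)
        }
      })
    })
    vapply(perms, function(p) {
      mean(v[cbind(idx, p)], na.rm = TRUE)
    }, numeric(1))
  }
}

new_pseudo_dist <- function(values, cfg, mode, lag_subset) {
  values <- values[is.finite(values)]
  n <- length(values)
  s <- sd(values)
  if (n < 2L || !is.finite(s) || s == 0) {
    stop_dyadsync(
      "Degenerate surrogate null: pseudo-synchrony values have zero spread.",
      "dyadsync_degenerate_null"
    )
  }
  if (n < 30L) {
    rlang::warn(sprintf(
      "Only %d surrogate values; the pseudo-synchrony SD is noisy below ~30.",
      n
    ), class = "dyadsync_few_surrogates")
  }
  structure(
    list(values = values, mean = mean(values), sd = s, n_surrogates = n,
         scheme = cfg$surrogate_scheme, mode = mode,
         lag_subset = lag_subset),
    class = "pseudo_dist"
  )
}

#' @export
print.pseudo_dist <- function(x, ...) {
  cat(sprintf(
    "<pseudo_dist> %s/%s, %d surrogates (%s): mean %.4g, sd %.4g\n",
    x$mode, x$lag_subset, x$n_surrogates, x$scheme, x$mean, x$sd
  ))
  invisible(x)
}

#' Surrogate (pseudo-synchrony) distribution for a segmented session
#'
#' Recomputes the session synchrony on deliberately mispaired segments of
#' the same dyad, yielding a null distribution that preserves each
#' signal's own autocorrelation while destroying the true temporal
#' pairing. Under the default all-pairs scheme the m - 1 cyclic rotations
#' of the therapist's segments are used; together they cover every ordered
#' mispairing (i, j), i != j, exactly once, and each rotation contributes
#' one surrogate session aggregate. The random-shuffles scheme instead
#' draws `cfg$n_shuffles` seeded fixed-point-free permutations.
#'
#' @param segments A segmented session from [segment_dyad()].
#' @param cfg A [sync_config()].
#' @param fs Sampling rate in Hz.
#' @param mode,lag_subset Aggregation variant, as in [aggregate_ccf()].
#' @return An object of class `pseudo_dist` with elements `values`,
#'   `mean`, `sd`, `n_surrogates`.
#' @export
surrogate_distribution <- function(segments, cfg = sync_config(), fs,
                                   mode = c("noabs", "abs"),
                                   lag_subset = c("all", "negative",
                                                  "positive")) {
  mode <- match.arg(mode)
  lag_subset <- match.arg(lag_subset)
  dims <- sync_dims(cfg, fs)
  r_arr <- lagged_cor_array(segments$patient, segments$therapist,
                            dims$lag_n)
  v <- segment_pair_values(r_arr, mode, lag_subset, cfg$fisher_z)
  new_pseudo_dist(surrogate_values(v, cfg), cfg, mode, lag_subset)
}

#' Synchrony effect size against a surrogate null
#'
#' `ES = (real synchrony - mean pseudo-synchrony) / SD of
#' pseudo-synchronies`: the distance of the observed session synchrony
#' from the centre of its own surrogate null, in null standard
#' deviations.
#'
#' @param real Observed session synchrony (from [aggregate_ccf()] or
#'   internally from [compute_synchrony()]).
#' @param pseudo A [`pseudo_dist`][surrogate_distribution].
#' @return The effect size (dimensionless).
#' @export
effect_size <- function(real, pseudo) {
  check_number(real, "real")
  if (!inherits(pseudo, "pseudo_dist")) {
    stop_dyadsync("`pseudo` must be a `pseudo_dist`.",
                  "dyadsync_invalid_input")
  }
  (real - pseudo$mean) / pseudo$sd
}

#' Surrogate synchrony effect sizes for one dyadic session
#'
#' The full per-session analysis: the aligned 20 Hz phasic series are cut
#' into 30-s segments, lagged Pearson cross-correlations (up to +/- 5 s)
#' are aggregated per segment and averaged over segments, and the
#' resulting session synchrony is contrasted with its surrogate
#' (mispaired-segment) null as an effect size. Six variants are returned:
#' `{abs, noabs} x {all lags, negative lags (patient-leading), positive
#' lags (therapist-leading)}`, each contrasted with a surrogate null
#' computed under the same mode and lag subset. Signed (`noabs`)
#' aggregation preserves polarity, so predominantly anti-phase sessions
#' yield negative `es_noabs` while `es_abs` stays positive.
#'
#' @param data A data frame with numeric columns `patient` and
#'   `therapist`: the two aligned phasic EDA series.
#' @param fs Sampling rate in Hz (nominally 20).
#' @param cfg A [sync_config()].
#' @param therapy_id,session_id Optional identifiers carried into the
#'   result.
#' @return A one-row tibble with `therapy_id`, `session_id`,
#'   `n_segments`, and for each variant `v` in `abs`, `noabs`,
#'   `abs_pt_lead`, `abs_th_lead`, `noabs_pt_lead`, `noabs_th_lead`:
#'   `es_<v>`, `real_<v>`, `pseudo_mean_<v>`, `pseudo_sd_<v>`.
#' @examples
#' sim <- simulate_dyad(sim_config(duration_seconds = 120, seed = 1))
#' compute_synchrony(sim$data, fs = 20)
#' @export
compute_synchrony <- function(data, fs = 20, cfg = sync_config(),
                              therapy_id = NA_character_,
                              session_id = NA_character_) {
  if (!is.data.frame(data) ||
      !all(c("patient", "therapist") %in% names(data))) {
    stop_dyadsync("`data` must have numeric `patient` and `therapist` columns.",
                  "dyadsync_invalid_input")
  }
  if (!inherits(cfg, "sync_config")) {
    stop_dyadsync("`cfg` must be a `sync_config`.", "dyadsync_invalid_input")
  }
  dims <- sync_dims(cfg, fs)
  segments <- segment_dyad(data$patient, data$therapist, fs,
                           cfg$segment_seconds)
  r_arr <- lagged_cor_array(segments$patient, segments$therapist,
                            dims$lag_n)

  variants <- list(
    abs = list(mode = "abs", lag_subset = "all"),
    noabs = list(mode = "noabs", lag_subset = "all"),
    abs_pt_lead = list(mode = "abs", lag_subset = "negative"),
    abs_th_lead = list(mode = "abs", lag_subset = "positive"),
    noabs_pt_lead = list(mode = "noabs", lag_subset = "negative"),
    noabs_th_lead = list(mode = "noabs", lag_subset = "positive")
  )

  out <- list(therapy_id = therapy_id, session_id = session_id,
              n_segments = segments$n_segments)
  for (nm in names(variants)) {
    vt <- variants[[nm]]
    v <- segment_pair_values(r_arr, vt$mode, vt$lag_subset, cfg$fisher_z)
    real_vals <- diag(v)
    real_vals <- real_vals[is.finite(real_vals)]
    if (length(real_vals) == 0L) {
      stop_dyadsync("No defined correlations in the requested lag subset.",
                    "dyadsync_undefined_aggregate")
    }
    real <- mean(real_vals)
    pseudo <- new_pseudo_dist(surrogate_values(v, cfg), cfg, vt$mode,
                              vt$lag_subset)
    out[[paste0("es_", nm)]] <- effect_size(real, pseudo)
    out[[paste0("real_", nm)]] <- real
    out[[paste0("pseudo_mean_", nm)]] <- pseudo$mean
    out[[paste0("pseudo_sd_", nm)]] <- pseudo$sd
  }
  tibble::as_tibble(out)
}
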