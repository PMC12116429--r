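#' Average lagged cross-correlation profile of a session
#'
#' Computes, and with `plot_lag_profile()` draws, the cross-correlation
#' function averaged over all segments of a session: one value per lag,
#' with negative lags meaning the patient's activity precedes the
#' therapist's. The shape of this profile is what the leading/following
#' decomposition summarizes — asymmetry towards negative lags indicates
#' patient-leading synchrony.
#'
#' @param data A data frame with `patient` and `therapist` columns.
#' @param fs Sampling rate in Hz.
#' @param cfg A [sync_config()].
#' @return `lag_profile()`: a tibble with `lag` (samples),
#'   `lag_seconds` and mean `r`; `plot_lag_profile()`: a ggplot.
#' @export
lag_profile <- function(data, fs = 20, cfg = sync_config()) {
  dims <- sync_dims(cfg, fs)
  segments <- segment_dyad(data$patient, data$therapist, fs,
                           cfg$segment_seconds)
  r_arr <- lagged_cor_array(segments$patient, segments$therapist,
                            dims$lag_n)
  real <- vapply(seq_len(dim(r_arr)[3]), function(li) {
    mean(diag(r_arr[, , li]), na.rm = TRUE)
  }, numeric(1))
  lags <- seq.int(-dims$lag_n, dims$lag_n)
  tibble(lag = lags, lag_seconds = lags / fs, r = real)
}

#' @rdname lag_profile
#' @export
plot_lag_profile <- function(data, fs = 20, cfg = sync_config()) {
  prof <- lag_profile(data, fs = fs, cfg = cfg)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$lag_seconds, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Lag (s; negative = patient leading)",
      y = "Mean cross-correlation",
      title = "Segment-averaged lagged cross-correlation"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a surrogate null distribution against the observed synchrony
#'
#' @param object A [`pseudo_dist`][surrogate_distribution].
#' @param real Optional observed session synchrony to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pseudo_dist <- function(object, real = NULL, ...) {
  df <- tibble(pseudo = object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pseudo)) +
    ggplot2::geom_histogram(bins = max(10L, min(40L, object$n_surrogates)),
                            fill = "grey70", colour = "grey40") +
    ggplot2::labs(
      x = sprintf("Pseudo-synchrony (%s, %s lags)", object$mode,
                  object$lag_subset),
      y = "Surrogate count",
      title = "Surrogate (pseudo-synchrony) null distribution"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(real)) {
    p <- p + ggplot2::geom_vline(xintercept = real, colour = "firebrick",
                                 linewidth = 1)
  }
  p
}

#' Distribution of per-session effect sizes across a study
#'
#' Histogram of one effect-size column over all sessions, split by the
#' sign of the signed (noabs) synchrony so the anti-phase minority is
#' visible.
#'
#' @param results Per-session synchrony results.
#' @param es Effect-size column to plot (default `"es_noabs"`).
#' @return A ggplot.
#' @export
plot_es_distribution <- function(results, es = "es_noabs") {
  if (!es %in% names(results)) {
    stop_dyadsync(sprintf("No column `%s` in `results`.", es),
                  "dyadsync_invalid_input")
  }
  df <- tibble(es = results[[es]],
               phase = ifelse(results[[es]] < 0, "anti-phase", "in-phase"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$es, fill = .data$phase)) +
    ggplot2::geom_histogram(bins = 30, colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_fill_manual(
      values = c("in-phase" = "steelblue", "anti-phase" = "indianred"),
      name = NULL
    ) +
    ggplot2::labs(x = es, y = "Sessions",
                  title = "Per-session synchrony effect sizes") +
    ggplot2::theme_minimal()
}
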