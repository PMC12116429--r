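#' Detect movement and electrode artifacts in raw skin conductance
#'
#' Flags abrupt signal changes using a session-adaptive threshold. The
#' absolute first differences of the signal are scanned with a sliding
#' window (20 samples at 2,000 Hz, i.e. 10 ms); the detection threshold is
#' the given percentile (default the 99th) of the sliding-window maxima of
#' those differences, floored at `floor` microsiemens so that near-constant
#' recordings are never flagged wholesale. Any single difference exceeding
#' the threshold is treated as an artifact and its enclosing window of
#' samples is flagged. The construction is deliberately conservative: on an
#' artifact-free recording the expected flagged fraction is well below 2%
#' of samples, while step discontinuities, spikes and electrode drop-outs
#' exceed the threshold by orders of magnitude.
#'
#' @param x Numeric vector of skin conductance samples (microsiemens).
#' @param window Sliding window length in samples (default 20; 10 ms at
#'   2,000 Hz). Must be at least 2 and shorter than the signal.
#' @param percentile Percentile (in (0, 1)) of the window maxima used as
#'   the adaptive threshold. Default 0.99.
#' @param floor Absolute lower bound for the threshold in microsiemens
#'   (default 0.01).
#' @return An object of class `artifact_mask`: a list with `flagged`
#'   (ordered integer sample indices), `threshold` (microsiemens) and
#'   `n_samples`. Use [tidy()] to get the flagged spans as a tibble.
#' @examples
#' x <- c(rep(0.5, 200), 6, rep(0.5, 200))
#' detect_artifacts(x, window = 20)
#' @export
detect_artifacts <- function(x, window = 20L, percentile = 0.99,
                             floor = 0.01) {
  check_numeric_vector(x, "x", min_length = 2L)
  check_number(window, "window", lower = 2)
  check_number(percentile, "percentile")
  check_number(floor, "floor", lower = 0)
  if (percentile <= 0 || percentile >= 1) {
    stop_dyadsync("`percentile` must lie strictly between 0 and 1.",
                  "dyadsync_invalid_parameter")
  }
  window <- as.integer(window)
  n <- length(x)
  if (n <= window) {
    stop_dyadsync("Signal must be longer than the sliding window.",
                  "dyadsync_invalid_input")
  }

  d <- abs(diff(x))
  k <- window - 1L
  win_max <- if (length(d) >= k) {
    zoo::rollmax(d, k, align = "left")
  } else {
    max(d)
  }
  threshold <- max(quantile(win_max, percentile, names = FALSE), floor)

  exceed <- which(d > threshold)
  flagged <- integer(0)
  if (length(exceed) > 0L) {
    half <- window %/% 2L
    starts <- pmax(exceed - half + 1L, 1L)
    ends <- pmin(exceed + half, n)
    flagged <- sort(unique(unlist(
      mapply(seq.int, starts, ends, SIMPLIFY = FALSE)
    )))
  }

  structure(
    list(flagged = flagged, threshold = threshold, n_samples = n),
    class = "artifact_mask"
  )
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf(
    "<artifact_mask> %d of %d samples flagged (threshold %.4g uS)\n",
    length(x$flagged), x$n_samples, x$threshold
  ))
  invisible(x)
}

#' Flagged artifact spans as a tibble
#'
#' Collapses an [`artifact_mask`][detect_artifacts] to contiguous runs,
#' one row per span, with columns `start_index`, `end_index`,
#' `threshold` — the mask-review export format.
#'
#' @param x An `artifact_mask`.
#' @param ... Unused.
#' @return A tibble of flagged spans.
#' @export
tidy.artifact_mask <- function(x, ...) {
  f <- x$flagged
  if (length(f) == 0L) {
    return(tibble(start_index = integer(), end_index = integer(),
                  threshold = double()))
  }
  breaks <- c(0L, which(diff(f) > 1L), length(f))
  tibble(
    start_index = f[breaks[-length(breaks)] + 1L],
    end_index = f[breaks[-1L]],
    threshold = x$threshold
  )
}

#' Repair flagged artifact samples by linear interpolation
#'
#' Flagged samples are replaced by linear interpolation between the
#' nearest unflagged neighbours; flagged runs at the start or end of the
#' recording are filled with the nearest unflagged value. Unflagged
#' samples are never altered.
#'
#' @param x Numeric vector of skin conductance samples.
#' @param mask An [`artifact_mask`][detect_artifacts], or an integer
#'   vector of flagged sample indices.
#' @return Numeric vector of the same length with flagged samples
#'   repaired.
#' @export
repair_artifacts <- function(x, mask) {
  check_numeric_vector(x, "x", finite = FALSE)
  flagged <- if (inherits(mask, "artifact_mask")) mask$flagged else
    as.integer(mask)
  if (length(flagged) == 0L) return(x)
  if (any(flagged < 1L | flagged > length(x))) {
    stop_dyadsync("Mask indices fall outside the signal.",
                  "dyadsync_invalid_input")
  }
  keep <- setdiff(seq_along(x), flagged)
  if (length(keep) == 0L) {
    stop_dyadsync("All samples are flagged; the signal cannot be repaired.",
                  "dyadsync_unrecoverable_signal")
  }
  x[flagged] <- approx(keep, x[keep], xout = flagged, rule = 2)$y
  x
}

#' Zero-phase low-pass filter for electrodermal activity
#'
#' Applies a zero-phase (forward-backward) Butterworth low-pass filter.
#' Zero-phase filtering matters here because any phase distortion would
#' bias the lead-lag estimates downstream. DC gain is 1, so tonic levels
#' are preserved, and the output has the same length as the input.
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz (default 1). Must be below the
#'   Nyquist frequency `fs / 2`.
#' @param order Butterworth filter order (default 4).
#' @return Filtered numeric vector, same length as `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff = 1, order = 4L) {
  check_numeric_vector(x, "x")
  check_number(fs, "fs", lower = 1e-12)
  check_number(cutoff, "cutoff", lower = 1e-12)
  check_number(order, "order", lower = 1)
  if (cutoff >= fs / 2) {
    stop_dyadsync("`cutoff` must be below the Nyquist frequency fs/2.",
                  "dyadsync_invalid_parameter")
  }
  bf <- signal::butter(as.integer(order), cutoff / (fs / 2), type = "low")
  n <- length(x)
  if (n < 2L) return(x)
  # Edge handling: remove the line through the endpoints, filter the
  # residual with odd-extension padding long enough for the filter
  # transient to die out, then restore the line. Keeps DC gain exactly 1
  # and the whole operation linear in x.
  baseline <- seq(x[1], x[n], length.out = n)
  r <- x - baseline
  padlen <- min(n - 1L, as.integer(ceiling(12 * fs / cutoff)))
  pre <- 2 * r[1] - r[seq.int(padlen + 1L, 2L)]
  post <- 2 * r[n] - r[seq.int(n - 1L, n - padlen)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, r, post)))
  y[seq.int(padlen + 1L, length.out = n)] + baseline
}

#' Reduce the sampling rate by integer decimation
#'
#' Keeps every `fs / target_fs`-th sample. The caller is responsible for
#' low-pass filtering below the target Nyquist frequency first (the
#' standard order of operations, and what [preprocess_eda()] does). Output
#' length is `floor(length(x) * target_fs / fs)`.
#'
#' @param x Numeric vector of samples.
#' @param fs Original sampling rate in Hz.
#' @param target_fs Target sampling rate in Hz (default 20). Must divide
#'   `fs`.
#' @return Numeric vector at the target rate.
#' @export
downsample_signal <- function(x, fs, target_fs = 20) {
  check_numeric_vector(x, "x")
  check_number(fs, "fs", lower = 1e-12)
  check_number(target_fs, "target_fs", lower = 1e-12)
  if (target_fs > fs) {
    stop_dyadsync("`target_fs` must not exceed `fs`.",
                  "dyadsync_invalid_parameter")
  }
  if (target_fs == fs) return(x)
  factor <- fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop_dyadsync("`fs` must be an integer multiple of `target_fs`.",
                  "dyadsync_invalid_parameter")
  }
  factor <- as.integer(round(factor))
  x[seq.int(1L, by = factor, length.out = length(x) %/% factor)]
}

#' Preprocess raw electrodermal recordings to clean 20 Hz phasic series
#'
#' The full preprocessing chain applied per recording: artifact detection
#' on the raw signal ([detect_artifacts()]), repair by interpolation
#' ([repair_artifacts()]), zero-phase 1 Hz low-pass ([lowpass_filter()])
#' and decimation to the analysis rate ([downsample_signal()], default
#' 20 Hz). The low-passed, decimated series is the phasic skin-conductance
#' analysis signal used by [compute_synchrony()].
#'
#' @param data A data frame with a numeric `eda` column (microsiemens) and
#'   any identifier columns among `therapy_id`, `session_id`, `role`; the
#'   chain is applied separately within each identifier combination.
#' @param fs Sampling rate of the input in Hz.
#' @param target_fs Analysis rate in Hz (default 20).
#' @param cutoff Low-pass cutoff in Hz (default 1).
#' @param artifact_window,artifact_percentile,artifact_floor Passed to
#'   [detect_artifacts()].
#' @return A tibble with the identifier columns, `sample` (1-based index
#'   at the target rate) and `eda`. The attribute `"artifact_spans"`
#'   holds a tibble of flagged spans (raw-signal indices) per recording.
#' @export
preprocess_eda <- function(data, fs, target_fs = 20, cutoff = 1,
                           artifact_window = 20L,
                           artifact_percentile = 0.99,
                           artifact_floor = 0.01) {
  if (!is.data.frame(data) || !"eda" %in% names(data)) {
    stop_dyadsync("`data` must be a data frame with an `eda` column.",
                  "dyadsync_invalid_input")
  }
  id_cols <- intersect(c("therapy_id", "session_id", "role"), names(data))
  grouped <- dplyr::group_by(data, dplyr::across(dplyr::all_of(id_cols)))
  spans <- list()
  out <- dplyr::group_modify(grouped, function(df, key) {
    mask <- detect_artifacts(df$eda, window = artifact_window,
                             percentile = artifact_percentile,
                             floor = artifact_floor)
    span_tbl <- tidy(mask)
    if (nrow(span_tbl) > 0L) {
      spans[[length(spans) + 1L]] <<- dplyr::bind_cols(key, span_tbl)
    }
    clean <- repair_artifacts(df$eda, mask)
    clean <- lowpass_filter(clean, fs = fs, cutoff = cutoff)
    clean <- downsample_signal(clean, fs = fs, target_fs = target_fs)
    tibble(sample = seq_along(clean), eda = clean)
  })
  out <- dplyr::ungroup(out)
  attr(out, "artifact_spans") <- if (length(spans) > 0L) {
    dplyr::bind_rows(spans)
  } else {
    tibble(start_index = integer(), end_index = integer(),
           threshold = double())
  }
  attr(out, "fs") <- target_fs
  out
}
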