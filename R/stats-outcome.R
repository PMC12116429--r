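#' Course-level regression of mean synchrony on pre/post outcome change
#'
#' Relates therapy-course outcome to synchrony: per-therapy change scores
#' (post - pre; for outcome-questionnaire scales a negative change means
#' improvement) of the three subscales are the predictors, and the mean
#' synchrony effect size across all sessions of the course is the
#' dependent variable, fitted by ordinary least squares. Only therapies
#' with both a pre and a post measurement enter. One-sample t-tests of
#' each change score against "no change" are reported alongside.
#'
#' @param outcomes A data frame with one row per therapy: `therapy_id`
#'   and, for each subscale in `subscales`, `<subscale>_pre` and
#'   `<subscale>_post` columns.
#' @param course_sync Per-therapy mean effect sizes, as returned by
#'   [per_course_means()].
#' @param es Name of the effect-size column used as the dependent
#'   variable (default `"es_noabs"`).
#' @param subscales Subscale stems (default `c("distress",
#'   "social_role", "interpersonal")`).
#' @return An object of class `sync_outcome_fit`. [tidy()] gives the OLS
#'   coefficient table, [glance()] the model summary, and the
#'   `change_tests` element the one-sample t-tests of the change scores.
#' @export
prepost_outcome_regression <- function(outcomes, course_sync,
                                       es = "es_noabs",
                                       subscales = c("distress",
                                                     "social_role",
                                                     "interpersonal")) {
  if (!is.data.frame(outcomes) || !"therapy_id" %in% names(outcomes)) {
    stop_dyadsync("`outcomes` must contain `therapy_id`.",
                  "dyadsync_invalid_input")
  }
  pre_cols <- paste0(subscales, "_pre")
  post_cols <- paste0(subscales, "_post")
  missing_cols <- setdiff(c(pre_cols, post_cols), names(outcomes))
  if (length(missing_cols) > 0L) {
    stop_dyadsync(paste0("Missing outcome columns: ",
                         paste(missing_cols, collapse = ", ")),
                  "dyadsync_invalid_input")
  }
  if (!es %in% names(course_sync)) {
    stop_dyadsync(sprintf("`course_sync` has no column `%s`.", es),
                  "dyadsync_invalid_input")
  }

  change_cols <- paste0("change_", subscales)
  df <- outcomes
  for (i in seq_along(subscales)) {
    df[[change_cols[i]]] <- df[[post_cols[i]]] - df[[pre_cols[i]]]
  }
  df <- dplyr::inner_join(
    df[, c("therapy_id", change_cols)],
    course_sync[, c("therapy_id", es)],
    by = "therapy_id"
  )
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 3L) {
    stop_dyadsync("Fewer than 3 therapies with complete pre/post outcomes.",
                  "dyadsync_insufficient_data")
  }

  change_tests <- purrr::map_dfr(seq_along(subscales), function(i) {
    ch <- df[[change_cols[i]]]
    if (sd(ch) == 0) {
      tibble(subscale = subscales[i], n = length(ch), mean = mean(ch),
             sd = 0, ci_low = NA_real_, ci_high = NA_real_, t = NA_real_,
             df = NA_real_, p = NA_real_, degenerate = TRUE)
    } else {
      dplyr::bind_cols(tibble(subscale = subscales[i]),
                       one_sample_t(ch), tibble(degenerate = FALSE))
    }
  })

  degenerate <- vapply(change_cols, function(cc) sd(df[[cc]]) == 0,
                       logical(1))
  usable <- change_cols[!degenerate]
  if (any(degenerate)) {
    rlang::warn(paste0("Zero-variance change score(s) dropped from the model: ",
                       paste(subscales[degenerate], collapse = ", ")),
                class = "dyadsync_degenerate_predictor")
  }
  fit <- if (length(usable) > 0L) {
    lm(reformulate(usable, response = es), data = df)
  } else {
    NULL
  }

  structure(
    list(fit = fit, data = df, es = es, n = nrow(df),
         change_tests = change_tests,
         dropped_predictors = subscales[degenerate],
         sign_convention = "change = post - pre (negative = improvement on outcome scales)"),
    class = "sync_outcome_fit"
  )
}

#' @export
print.sync_outcome_fit <- function(x, ...) {
  cat(sprintf("<sync_outcome_fit> %s ~ pre/post changes, %d therapies\n",
              x$es, x$n))
  cat(" ", x$sign_convention, "\n")
  if (is.null(x$fit)) {
    cat("  All change scores degenerate; no regression fitted.\n")
  } else {
    print(tidy(x))
  }
  invisible(x)
}

#' @rdname prepost_outcome_regression
#' @param x,object A `sync_outcome_fit`.
#' @param ... Unused.
#' @export
tidy.sync_outcome_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(term = character(), estimate = double(),
                  std_error = double(), t = double(), p = double()))
  }
  co <- summary(x$fit)$coefficients
  tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    t = co[, "t value"],
    p = co[, "Pr(>|t|)"]
  )
}

#' @rdname prepost_outcome_regression
#' @export
glance.sync_outcome_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(n = x$n, r_squared = NA_real_, adj_r_squared = NA_real_,
                  p = NA_real_, degenerate = TRUE))
  }
  sm <- summary(x$fit)
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  tibble(n = x$n, r_squared = sm$r.squared,
         adj_r_squared = sm$adj.r.squared, p = p,
         degenerate = length(x$dropped_predictors) > 0L)
}
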