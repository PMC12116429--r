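#' Random-intercept model of session-level synchrony
#'
#' Fits a linear mixed model with the given fixed predictors and a random
#' intercept per therapy course (sessions nested in courses), estimated
#' by REML via \pkg{lmerTest}. Incomplete sessions are dropped listwise.
#' Reported alongside the fixed-effect estimates and t-values are the
#' random-intercept share of the total (intercept + residual) variance
#' and Nakagawa-style marginal and conditional pseudo-R-squared values,
#' all as percentages.
#'
#' @param data A data frame of session-level records.
#' @param response Name of the dependent variable (a synchrony effect
#'   size column such as `"es_noabs_pt_lead"`).
#' @param predictors Character vector of fixed-effect column names
#'   (alliance/session scales).
#' @param cluster Name of the grouping column (default `"therapy_id"`).
#' @return An object of class `sync_mixed`. Use [tidy()] for the
#'   fixed-effect table (term, estimate, std_error, t, df, p) and
#'   [glance()] for `n_obs`, `n_clusters`, `random_intercept_pct`,
#'   `r2_marginal_pct`, `r2_conditional_pct`, `singular`.
#' @examples
#' \donttest{
#' study <- simulate_study(n_therapies = 4, sessions_per_therapy = 4,
#'                         cfg = sim_config(duration_seconds = 240, seed = 1),
#'                         seed = 1)
#' res <- dplyr::left_join(study$synchrony, study$scores,
#'                         by = c("therapy_id", "session_id"))
#' fit <- fit_random_intercept(res, "es_noabs",
#'                             c("wai_bond_th", "wai_goal_th"))
#' tidy(fit)
#' }
#' @export
fit_random_intercept <- function(data, response, predictors,
                                 cluster = "therapy_id") {
  if (!is.data.frame(data)) {
    stop_dyadsync("`data` must be a data frame.", "dyadsync_invalid_input")
  }
  used <- c(response, predictors, cluster)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0L) {
    stop_dyadsync(paste0("Missing columns: ",
                         paste(missing_cols, collapse = ", ")),
                  "dyadsync_invalid_input")
  }
  df <- data[complete.cases(data[used]), used, drop = FALSE]
  if (dplyr::n_distinct(df[[cluster]]) < 2L) {
    stop_dyadsync("Need at least 2 clusters for a random intercept.",
                  "dyadsync_insufficient_data")
  }
  fml <- stats::as.formula(paste(
    response, "~", paste(predictors, collapse = " + "),
    "+ (1 |", cluster, ")"
  ))
  fit <- lmerTest::lmer(fml, data = df, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular) {
    rlang::warn("Random-intercept variance is (near) zero; fit is singular.",
                class = "dyadsync_singular_fit")
  }

  sm <- summary(fit)
  co <- sm$coefficients
  coefs <- tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    std_error = unname(co[, "Std. Error"]),
    t = unname(co[, "t value"]),
    df = unname(co[, "df"]),
    p = unname(co[, "Pr(>|t|)"])
  )

  vc <- as.data.frame(lme4::VarCorr(fit))
  var_int <- vc$vcov[vc$grp == cluster]
  var_res <- vc$vcov[vc$grp == "Residual"]
  var_fix <- var(as.numeric(
    stats::model.matrix(fit) %*% lme4::fixef(fit)
  ))
  total <- var_fix + var_int + var_res

  structure(
    list(
      fit = fit,
      coefficients = coefs,
      response = response,
      predictors = predictors,
      cluster = cluster,
      data = df,
      n_obs = nrow(df),
      n_clusters = dplyr::n_distinct(df[[cluster]]),
      random_intercept_pct = 100 * var_int / (var_int + var_res),
      r2_marginal_pct = 100 * var_fix / total,
      r2_conditional_pct = 100 * (var_fix + var_int) / total,
      singular = singular
    ),
    class = "sync_mixed"
  )
}

#' @export
print.sync_mixed <- function(x, ...) {
  cat(sprintf("<sync_mixed> %s ~ %s + (1 | %s)\n", x$response,
              paste(x$predictors, collapse = " + "), x$cluster))
  cat(sprintf("  N = %d sessions in %d courses; random intercept %.1f%% of variance; R2 marginal %.1f%%, conditional %.1f%%%s\n",
              x$n_obs, x$n_clusters, x$random_intercept_pct,
              x$r2_marginal_pct, x$r2_conditional_pct,
              if (x$singular) " (singular)" else ""))
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_random_intercept
#' @param x,object A `sync_mixed` object.
#' @param ... Unused.
#' @export
tidy.sync_mixed <- function(x, ...) {
  x$coefficients
}

#' @rdname fit_random_intercept
#' @export
glance.sync_mixed <- function(x, ...) {
  tibble(
    n_obs = x$n_obs,
    n_clusters = x$n_clusters,
    random_intercept_pct = x$random_intercept_pct,
    r2_marginal_pct = x$r2_marginal_pct,
    r2_conditional_pct = x$r2_conditional_pct,
    singular = x$singular
  )
}

#' Two-stage refit with significant predictors only
#'
#' Refits a [fit_random_intercept()] model keeping only the predictors
#' whose coefficient p-value is below `alpha` in the full model (the
#' intercept is always kept). If no predictor survives, `NULL` is
#' returned with a message — the "not entered" outcome of the two-stage
#' protocol.
#'
#' @param object A `sync_mixed` fit (the full model).
#' @param alpha Per-coefficient significance threshold (default 0.05).
#' @return A `sync_mixed` fit of the reduced model, or `NULL`.
#' @export
refit_significant <- function(object, alpha = 0.05) {
  if (!inherits(object, "sync_mixed")) {
    stop_dyadsync("`object` must be a `sync_mixed` fit.",
                  "dyadsync_invalid_input")
  }
  keep <- object$coefficients |>
    dplyr::filter(.data$term != "(Intercept)", .data$p < alpha) |>
    dplyr::pull("term")
  if (length(keep) == 0L) {
    message("No significant predictors at alpha = ", alpha,
            "; reduced model not entered.")
    return(NULL)
  }
  fit_random_intercept(object$data, object$response, keep,
                       cluster = object$cluster)
}
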