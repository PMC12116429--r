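#' One-sample t-test as a tidy row
#'
#' Classical one-sample t-test of a vector against a null value, returned
#' as a one-row tibble in the summary-table layout used throughout the
#' package (n, mean, SD, 95% CI, t, df, p). Used to test per-session and
#' per-course synchrony effect sizes against the null hypothesis of no
#' synchrony (mu0 = 0).
#'
#' @param values Numeric vector, length >= 2, finite.
#' @param mu0 Null value (default 0).
#' @param conf_level Confidence level for the CI (default 0.95).
#' @return A one-row tibble with columns `n`, `mean`, `sd`, `ci_low`,
#'   `ci_high`, `t`, `df`, `p`.
#' @export
one_sample_t <- function(values, mu0 = 0, conf_level = 0.95) {
  check_numeric_vector(values, "values", min_length = 2L)
  check_number(mu0, "mu0")
  if (sd(values) <= 1e-10 * max(1, abs(mean(values)))) {
    stop_dyadsync("All values are (essentially) identical; the t-test is degenerate.",
                  "dyadsync_degenerate_test")
  }
  ht <- t.test(values, mu = mu0, conf.level = conf_level)
  tibble(
    n = length(values),
    mean = mean(values),
    sd = sd(values),
    ci_low = ht$conf.int[1],
    ci_high = ht$conf.int[2],
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value
  )
}

#' Paired t-test as a tidy row
#'
#' One-sample t-test on the element-wise differences `a - b`. Used to
#' compare patient-leading against therapist-leading synchrony within
#' sessions.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @param conf_level Confidence level for the CI (default 0.95).
#' @return A one-row tibble as in [one_sample_t()]; `mean` is the mean
#'   difference.
#' @export
paired_t <- function(a, b, conf_level = 0.95) {
  check_numeric_vector(a, "a", min_length = 2L)
  check_numeric_vector(b, "b", min_length = 2L)
  if (length(a) != length(b)) {
    stop_dyadsync("`a` and `b` must have equal length.",
                  "dyadsync_invalid_input")
  }
  one_sample_t(a - b, mu0 = 0, conf_level = conf_level)
}

#' Cluster-wise centering of session-level values
#'
#' Removes between-cluster (between-therapy-course) variance from a
#' session-level variable. The default pure within-cluster centering
#' subtracts each cluster's mean; `restore_grand_mean = TRUE` adds the
#' grand mean back so the overall level is preserved. Within-cluster
#' differences are untouched either way, but comparing two pure-centered
#' variables discards their overall level difference (both means become
#' exactly zero), so paired comparisons of centered variables must use
#' `restore_grand_mean = TRUE`.
#'
#' @param values Numeric vector.
#' @param clusters Cluster (therapy course) identifier per value.
#' @param restore_grand_mean Add the grand mean back? Default `FALSE`.
#' @return Numeric vector of centered values.
#' @export
cluster_center <- function(values, clusters, restore_grand_mean = FALSE) {
  check_numeric_vector(values, "values")
  if (length(clusters) != length(values)) {
    stop_dyadsync("`clusters` must match `values` in length.",
                  "dyadsync_invalid_input")
  }
  centered <- values - ave(values, clusters)
  if (isTRUE(restore_grand_mean)) centered <- centered + mean(values)
  centered
}

#' Pearson correlation between two session-level variables
#'
#' @param a,b Numeric vectors of equal length >= 3, finite.
#' @return Pearson's r; `NA` (with a warning) if either variable has zero
#'   variance.
#' @export
pairwise_pearson <- function(a, b) {
  check_numeric_vector(a, "a", min_length = 3L)
  check_numeric_vector(b, "b", min_length = 3L)
  if (length(a) != length(b)) {
    stop_dyadsync("`a` and `b` must have equal length.",
                  "dyadsync_invalid_input")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    rlang::warn("Zero variance: correlation undefined.",
                class = "dyadsync_zero_variance")
    return(NA_real_)
  }
  cor(a, b)
}

#' Mean effect sizes per therapy course
#'
#' Unweighted mean of every `es_*` (and `real_*`) column per
#' `therapy_id`, the course-level aggregation used both for the
#' course-level one-sample t-tests and as the dependent variable of the
#' pre/post outcome regressions.
#'
#' @param results A tibble of per-session synchrony results (from
#'   [compute_synchrony()] rows bound together) with a `therapy_id`
#'   column.
#' @return A tibble with one row per therapy: `therapy_id`,
#'   `n_sessions`, and the mean of each `es_*`/`real_*` column.
#' @export
per_course_means <- function(results) {
  if (!is.data.frame(results) || !"therapy_id" %in% names(results)) {
    stop_dyadsync("`results` must contain a `therapy_id` column.",
                  "dyadsync_invalid_input")
  }
  results |>
    dplyr::group_by(.data$therapy_id) |>
    dplyr::summarise(
      n_sessions = dplyr::n(),
      dplyr::across(dplyr::starts_with("es_") | dplyr::starts_with("real_"),
                    mean),
      .groups = "drop"
    )
}

#' Summary table of synchrony effect sizes
#'
#' Builds the standard descriptive/inferential summary of a study's
#' per-session effect sizes: session-level one-sample t-tests of
#' `es_abs` and `es_noabs` against zero; the patient-leading vs
#' therapist-leading components with their paired t-test; course-level
#' means with one-sample t-tests; and the cluster-wise centered
#' (grand mean restored) leading components with the paired t-test
#' repeated on them, removing between-course variance from the
#' within-session comparison.
#'
#' @param results Per-session synchrony results with `therapy_id` and the
#'   six `es_*` columns.
#' @param conf_level Confidence level for CIs (default 0.95).
#' @return A tibble with columns `measure`, `level`, `n`, `mean`, `sd`,
#'   `ci_low`, `ci_high`, `p`, `p_type`. `p_type` is `"vs_zero"` for
#'   one-sample tests and `"pt_vs_th"` for the paired patient- vs
#'   therapist-leading comparison (reported on the patient row).
#' @export
summarize_synchrony <- function(results, conf_level = 0.95) {
  needed <- c("therapy_id", "es_abs", "es_noabs", "es_abs_pt_lead",
              "es_abs_th_lead", "es_noabs_pt_lead", "es_noabs_th_lead")
  if (!is.data.frame(results) || !all(needed %in% names(results))) {
    stop_dyadsync("`results` must contain therapy_id and the six es_* columns.",
                  "dyadsync_invalid_input")
  }
  row_of <- function(measure, level, tt, p = tt$p, p_type = "vs_zero") {
    tibble(measure = measure, level = level, n = tt$n, mean = tt$mean,
           sd = tt$sd, ci_low = tt$ci_low, ci_high = tt$ci_high,
           p = p, p_type = p_type)
  }
  # A degenerate (zero-variance) column yields a descriptive row with NA
  # inference rather than failing the whole summary.
  safe_t <- function(values) {
    tryCatch(
      one_sample_t(values, conf_level = conf_level),
      dyadsync_degenerate_test = function(e) {
        tibble(n = length(values), mean = mean(values), sd = sd(values),
               ci_low = NA_real_, ci_high = NA_real_, t = NA_real_,
               df = NA_real_, p = NA_real_)
      }
    )
  }
  safe_p <- function(expr) {
    tryCatch(expr, dyadsync_degenerate_test = function(e) NA_real_)
  }
  desc_row <- function(measure, level, values, p = NA_real_,
                       p_type = NA_character_) {
    row_of(measure, level, safe_t(values), p = p, p_type = p_type)
  }
  course <- per_course_means(results)

  pt_abs <- results$es_abs_pt_lead
  th_abs <- results$es_abs_th_lead
  pt_no <- results$es_noabs_pt_lead
  th_no <- results$es_noabs_th_lead
  cl <- results$therapy_id
  pt_abs_c <- cluster_center(pt_abs, cl, restore_grand_mean = TRUE)
  th_abs_c <- cluster_center(th_abs, cl, restore_grand_mean = TRUE)
  pt_no_c <- cluster_center(pt_no, cl, restore_grand_mean = TRUE)
  th_no_c <- cluster_center(th_no, cl, restore_grand_mean = TRUE)

  dplyr::bind_rows(
    desc_row("es_abs", "session", results$es_abs,
             p = safe_p(one_sample_t(results$es_abs)$p), p_type = "vs_zero"),
    desc_row("es_noabs", "session", results$es_noabs,
             p = safe_p(one_sample_t(results$es_noabs)$p), p_type = "vs_zero"),
    desc_row("es_abs_pt_lead", "session", pt_abs,
             p = safe_p(paired_t(pt_abs, th_abs)$p), p_type = "pt_vs_th"),
    desc_row("es_abs_th_lead", "session", th_abs),
    desc_row("es_noabs_pt_lead", "session", pt_no,
             p = safe_p(paired_t(pt_no, th_no)$p), p_type = "pt_vs_th"),
    desc_row("es_noabs_th_lead", "session", th_no),
    desc_row("mean_es_abs", "course", course$es_abs,
             p = safe_p(one_sample_t(course$es_abs)$p), p_type = "vs_zero"),
    desc_row("mean_es_noabs", "course", course$es_noabs,
             p = safe_p(one_sample_t(course$es_noabs)$p), p_type = "vs_zero"),
    desc_row("es_abs_pt_lead_centered", "session", pt_abs_c,
             p = safe_p(paired_t(pt_abs_c, th_abs_c)$p), p_type = "pt_vs_th"),
    desc_row("es_abs_th_lead_centered", "session", th_abs_c),
    desc_row("es_noabs_pt_lead_centered", "session", pt_no_c,
             p = safe_p(paired_t(pt_no_c, th_no_c)$p), p_type = "pt_vs_th"),
    desc_row("es_noabs_th_lead_centered", "session", th_no_c)
  )
}
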