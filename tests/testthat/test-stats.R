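test_that("one_sample_t matches the textbook computation", {
  set.seed(31)
  v <- rnorm(40, mean = 0.8)
  tt <- one_sample_t(v, mu0 = 0.5)
  n <- length(v)
  t_ref <- (mean(v) - 0.5) / (sd(v) / sqrt(n))
  expect_equal(tt$t, t_ref, tolerance = 1e-12)
  expect_equal(tt$df, n - 1)
  expect_equal(tt$p, 2 * stats::pt(-abs(t_ref), n - 1), tolerance = 1e-12)
  half <- stats::qt(0.975, n - 1) * sd(v) / sqrt(n)
  expect_equal(tt$ci_low, mean(v) - half, tolerance = 1e-12)
  expect_equal(tt$ci_high, mean(v) + half, tolerance = 1e-12)
})

test_that("one_sample_t handles hand-checkable and degenerate cases", {
  tt <- one_sample_t(c(1, 2, 3), mu0 = 2)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  expect_error(one_sample_t(rep(5, 10)), class = "dyadsync_degenerate_test")
  set.seed(32)
  strong <- rnorm(100, mean = 1, sd = 1)
  expect_lt(one_sample_t(strong)$p, 0.001)
})

test_that("paired_t is the one-sample test of the differences", {
  set.seed(33)
  a <- rnorm(30)
  b <- a + rnorm(30, 0.3, 0.2)
  expect_equal(paired_t(a, b), one_sample_t(a - b))
  expect_error(paired_t(a, a), class = "dyadsync_degenerate_test")
  expect_error(paired_t(a, a + 1), class = "dyadsync_degenerate_test")
  # independent samples rarely produce extreme t
  expect_lt(abs(paired_t(rnorm(200), rnorm(200))$t), 5)
})

test_that("cluster_center removes between-cluster variance only", {
  v <- c(0, 2, 10, 12)
  cl <- c("a", "a", "b", "b")
  expect_equal(cluster_center(v, cl), c(-1, 1, -1, 1))
  # between-cluster variance of the centered variable is zero
  centered <- cluster_center(v, cl)
  expect_equal(as.numeric(tapply(centered, cl, mean)), c(0, 0))
  # grand-mean restoration shifts but keeps within-cluster differences
  restored <- cluster_center(v, cl, restore_grand_mean = TRUE)
  expect_equal(restored, c(-1, 1, -1, 1) + 6)
  # single cluster: centered values equal the grand-mean-restored original
  single <- cluster_center(v, rep("a", 4), restore_grand_mean = TRUE)
  expect_equal(single, v)
  # paired differences are invariant to centering
  w <- c(1, 5, 2, 20)
  expect_equal(cluster_center(v, cl) - cluster_center(w, cl),
               (v - w) - ave(v - w, cl))
})

test_that("pairwise_pearson matches cor and warns on zero variance", {
  set.seed(34)
  a <- rnorm(50)
  b <- rnorm(50)
  expect_equal(pairwise_pearson(a, b), cor(a, b))
  expect_warning(r <- pairwise_pearson(rep(1, 10), rnorm(10)),
                 class = "dyadsync_zero_variance")
  expect_true(is.na(r))
})

test_that("per_course_means averages every effect-size column per therapy", {
  df <- tibble::tibble(
    therapy_id = c("T1", "T1", "T2"),
    session_id = c("S1", "S2", "S1"),
    es_abs = c(1, 3, 5),
    es_noabs = c(0, 2, -1),
    real_abs = c(0.1, 0.3, 0.2)
  )
  cm <- per_course_means(df)
  expect_identical(cm$therapy_id, c("T1", "T2"))
  expect_identical(cm$n_sessions, c(2L, 1L))
  expect_equal(cm$es_abs, c(2, 5))
  expect_equal(cm$es_noabs, c(1, -1))
  expect_equal(cm$real_abs, c(0.2, 0.2))
})

test_that("summarize_synchrony lays out session, course and centered rows", {
  set.seed(35)
  n <- 40
  df <- tibble::tibble(
    therapy_id = rep(sprintf("T%d", 1:8), each = 5),
    es_abs = rnorm(n, 3), es_noabs = rnorm(n, 2),
    es_abs_pt_lead = rnorm(n, 2.2), es_abs_th_lead = rnorm(n, 2.0),
    es_noabs_pt_lead = rnorm(n, 1.5), es_noabs_th_lead = rnorm(n, 1.4)
  )
  sm <- summarize_synchrony(df)
  expect_setequal(
    sm$measure,
    c("es_abs", "es_noabs", "es_abs_pt_lead", "es_abs_th_lead",
      "es_noabs_pt_lead", "es_noabs_th_lead", "mean_es_abs",
      "mean_es_noabs", "es_abs_pt_lead_centered", "es_abs_th_lead_centered",
      "es_noabs_pt_lead_centered", "es_noabs_th_lead_centered")
  )
  expect_equal(sm$mean[sm$measure == "es_abs"], mean(df$es_abs))
  expect_identical(sm$n[sm$measure == "mean_es_abs"], 8L)
  # centering restores the grand mean, so the level is preserved while
  # between-course variance is removed from the paired comparison
  expect_equal(sm$mean[sm$measure == "es_abs_pt_lead_centered"],
               sm$mean[sm$measure == "es_abs_pt_lead"], tolerance = 1e-12)
  expect_true(is.finite(sm$p[sm$measure == "es_abs_pt_lead_centered"]))
  expect_identical(sm$p_type[sm$measure == "es_abs_pt_lead"], "pt_vs_th")
})

test_that("fit_random_intercept recovers a known fixed effect", {
  set.seed(36)
  n_cl <- 21
  per <- 14
  df <- tibble::tibble(
    therapy_id = rep(sprintf("T%02d", seq_len(n_cl)), each = per),
    x = rnorm(n_cl * per)
  )
  offsets <- rnorm(n_cl, 0, 1)
  df$y <- 2 + 1.5 * df$x + offsets[as.integer(factor(df$therapy_id))] +
    rnorm(nrow(df), 0, 1)
  fit <- fit_random_intercept(df, "y", "x")
  expect_s3_class(fit, "sync_mixed")
  co <- tidy(fit)
  est <- co$estimate[co$term == "x"]
  expect_gt(est, 1.2)
  expect_lt(est, 1.8)
  expect_gt(co$t[co$term == "x"], 5)
  g <- glance(fit)
  expect_equal(g$n_obs, n_cl * per)
  expect_equal(g$n_clusters, n_cl)
  # substantial cluster variance is reported as a substantial share
  expect_gt(g$random_intercept_pct, 20)
  expect_gte(g$r2_conditional_pct, g$r2_marginal_pct)
})

test_that("fit_random_intercept reports near-zero share without cluster effects", {
  set.seed(37)
  df <- tibble::tibble(
    therapy_id = rep(sprintf("T%02d", 1:15), each = 10),
    x = rnorm(150)
  )
  df$y <- 1 + 0.5 * df$x + rnorm(150)
  fit <- suppressWarnings(fit_random_intercept(df, "y", "x"))
  expect_lt(glance(fit)$random_intercept_pct, 5)
  # and the fixed effects then agree with plain OLS
  ols <- unname(coef(lm(y ~ x, data = df)))
  co <- tidy(fit)
  expect_equal(co$estimate[co$term == "x"], ols[2], tolerance = 0.05)
})

test_that("mixed-model t-statistics are calibrated under the null", {
  set.seed(38)
  hits <- 0L
  n_fit <- 100L
  for (i in seq_len(n_fit)) {
    df <- tibble::tibble(
      therapy_id = rep(sprintf("T%02d", 1:10), each = 8),
      x = rnorm(80)
    )
    df$y <- rnorm(10, 0, 0.7)[as.integer(factor(df$therapy_id))] +
      rnorm(80)
    fit <- suppressWarnings(fit_random_intercept(df, "y", "x"))
    co <- tidy(fit)
    if (abs(co$t[co$term == "x"]) > 2) hits <- hits + 1L
  }
  expect_gte(n_fit - hits, 90L)
})

test_that("fit_random_intercept validates inputs and degenerate designs", {
  df <- tibble::tibble(therapy_id = rep("T01", 10), x = rnorm(10),
                       y = rnorm(10))
  expect_error(fit_random_intercept(df, "y", "x"),
               class = "dyadsync_insufficient_data")
  expect_error(
    fit_random_intercept(tibble::tibble(a = 1), "y", "x"),
    class = "dyadsync_invalid_input"
  )
  # missing values are dropped listwise, with the count reported
  df2 <- tibble::tibble(
    therapy_id = rep(c("T01", "T02", "T03"), each = 10),
    x = rnorm(30), y = rnorm(30)
  )
  df2$x[c(3, 17)] <- NA
  fit <- suppressWarnings(fit_random_intercept(df2, "y", "x"))
  expect_identical(glance(fit)$n_obs, 28L)
})

test_that("refit_significant keeps only p < .05 predictors", {
  set.seed(39)
  df <- tibble::tibble(
    therapy_id = rep(sprintf("T%02d", 1:12), each = 12)
  )
  df$x1 <- rnorm(nrow(df))
  df$x2 <- rnorm(nrow(df))
  df$y <- 1 + 1.2 * df$x1 +
    rnorm(12, 0, 0.8)[as.integer(factor(df$therapy_id))] +
    rnorm(nrow(df))
  fit <- suppressWarnings(fit_random_intercept(df, "y", c("x1", "x2")))
  red <- suppressWarnings(refit_significant(fit))
  expect_s3_class(red, "sync_mixed")
  expect_setequal(setdiff(tidy(red)$term, "(Intercept)"), "x1")
  # with no significant predictor, nothing enters the second stage
  df$y2 <- rnorm(12, 0, 0.8)[as.integer(factor(df$therapy_id))] +
    rnorm(nrow(df))
  fit2 <- suppressWarnings(fit_random_intercept(df, "y2", c("x1", "x2")))
  expect_null(suppressMessages(refit_significant(fit2)))
})

test_that("prepost_outcome_regression recovers a known association sign", {
  set.seed(40)
  recovered <- 0L
  for (i in 1:100) {
    n <- 19
    outcomes <- tibble::tibble(
      therapy_id = sprintf("T%02d", 1:n),
      distress_pre = rnorm(n, 50, 8),
      social_role_pre = rnorm(n, 18, 4),
      interpersonal_pre = rnorm(n, 22, 5)
    )
    change <- rnorm(n, -12, 6)
    outcomes$distress_post <- outcomes$distress_pre + change
    outcomes$social_role_post <- outcomes$social_role_pre + rnorm(n, -3, 3)
    outcomes$interpersonal_post <- outcomes$interpersonal_pre +
      rnorm(n, -3, 3)
    course <- tibble::tibble(
      therapy_id = outcomes$therapy_id,
      es_noabs = 2 - 0.1 * change + rnorm(n, 0, 0.5)
    )
    fit <- prepost_outcome_regression(outcomes, course)
    co <- tidy(fit)
    if (co$estimate[co$term == "change_distress"] < 0) {
      recovered <- recovered + 1L
    }
  }
  # more distress reduction (more negative change) goes with more synchrony
  expect_gte(recovered, 80L)
})

test_that("prepost_outcome_regression is calibrated under the null", {
  set.seed(41)
  sig <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    n <- 19
    outcomes <- tibble::tibble(
      therapy_id = sprintf("T%02d", 1:n),
      distress_pre = rnorm(n, 50, 8),
      social_role_pre = rnorm(n, 18, 4),
      interpersonal_pre = rnorm(n, 22, 5)
    )
    outcomes$distress_post <- outcomes$distress_pre + rnorm(n, -12, 6)
    outcomes$social_role_post <- outcomes$social_role_pre + rnorm(n, -3, 3)
    outcomes$interpersonal_post <- outcomes$interpersonal_pre +
      rnorm(n, -3, 3)
    course <- tibble::tibble(therapy_id = outcomes$therapy_id,
                             es_noabs = rnorm(n, 2, 1))
    fit <- prepost_outcome_regression(outcomes, course)
    co <- tidy(fit)
    if (any(co$p[co$term != "(Intercept)"] < 0.05)) sig <- sig + 1L
  }
  # three predictors at alpha = .05: familywise rate must stay modest
  expect_gte(sig / n_rep, 0.01)
  expect_lte(sig / n_rep, 0.30)
})

test_that("prepost_outcome_regression handles degenerate and sparse inputs", {
  outcomes <- tibble::tibble(
    therapy_id = c("T1", "T2"),
    distress_pre = c(50, 52), distress_post = c(40, 41),
    social_role_pre = c(18, 19), social_role_post = c(15, 15),
    interpersonal_pre = c(20, 21), interpersonal_post = c(18, 18)
  )
  course <- tibble::tibble(therapy_id = c("T1", "T2"), es_noabs = c(2, 3))
  expect_error(prepost_outcome_regression(outcomes, course),
               class = "dyadsync_insufficient_data")

  # identical change everywhere: flagged and dropped, not silently fit
  n <- 6
  outcomes2 <- tibble::tibble(
    therapy_id = sprintf("T%d", 1:n),
    distress_pre = rnorm(n, 50), distress_post = NA_real_,
    social_role_pre = rnorm(n, 18), social_role_post = NA_real_,
    interpersonal_pre = rnorm(n, 22), interpersonal_post = NA_real_
  )
  outcomes2$distress_post <- outcomes2$distress_pre - 10
  outcomes2$social_role_post <- outcomes2$social_role_pre + rnorm(n, -3)
  outcomes2$interpersonal_post <- outcomes2$interpersonal_pre +
    rnorm(n, -3)
  course2 <- tibble::tibble(therapy_id = outcomes2$therapy_id,
                            es_noabs = rnorm(n, 2))
  expect_warning(
    fit <- prepost_outcome_regression(outcomes2, course2),
    class = "dyadsync_degenerate_predictor"
  )
  expect_identical(fit$dropped_predictors, "distress")
  expect_true(fit$change_tests$degenerate[
    fit$change_tests$subscale == "distress"])
  expect_false("change_distress" %in% tidy(fit)$term)
})
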