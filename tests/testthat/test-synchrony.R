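test_that("segment_dyad cuts sessions into full 30-s segments", {
  seg <- segment_dyad(rnorm(3000), rnorm(3000), fs = 20)
  expect_identical(seg$n_segments, 5L)
  expect_identical(seg$n_dropped, 0L)
  expect_identical(dim(seg$patient), c(600L, 5L))

  seg2 <- segment_dyad(rnorm(3599), rnorm(3599), fs = 20)
  expect_identical(seg2$n_segments, 5L)
  expect_identical(seg2$n_dropped, 599L)

  expect_error(segment_dyad(rnorm(700), rnorm(700), fs = 20),
               class = "dyadsync_session_too_short")
})

test_that("segment_dyad trims channels to their common length", {
  p <- rnorm(1300)
  t2 <- rnorm(1250)
  seg <- segment_dyad(p, t2, fs = 20)
  expect_identical(seg$n_segments, 2L)
  expect_identical(seg$patient[, 1], p[1:600])
  expect_identical(seg$therapist[, 2], t2[601:1200])
})

test_that("crosscorr_segment matches stats::cor at every lag", {
  set.seed(7)
  x <- rnorm(120)
  y <- rnorm(120)
  ccf <- crosscorr_segment(x, y, max_lag = 5)
  expect_identical(ccf$lag, -5:5)
  for (i in seq_len(nrow(ccf))) {
    l <- ccf$lag[i]
    ref <- if (l < 0) {
      stats::cor(x[1:(120 + l)], y[(1 - l):120])
    } else if (l > 0) {
      stats::cor(x[(1 + l):120], y[1:(120 - l)])
    } else {
      stats::cor(x, y)
    }
    expect_equal(ccf$r[i], ref, tolerance = 1e-12)
  }
})

test_that("crosscorr_segment sign convention: negative lag = patient leads", {
  set.seed(8)
  x <- rnorm(200)
  y <- c(rnorm(3), x[1:197])  # therapist echoes patient 3 samples later
  ccf <- crosscorr_segment(x, y, max_lag = 6)
  expect_identical(ccf$lag[which.max(ccf$r)], -3L)
  expect_gt(max(ccf$r), 0.99)
  # identical series peak at lag 0 with r = 1; anti-phase gives r = -1
  self <- crosscorr_segment(x, x, max_lag = 3)
  expect_equal(self$r[self$lag == 0], 1, tolerance = 1e-12)
  anti <- crosscorr_segment(x, -x, max_lag = 3)
  expect_equal(anti$r[anti$lag == 0], -1, tolerance = 1e-12)
})

test_that("crosscorr_segment yields NA on zero-variance overlaps", {
  ccf <- crosscorr_segment(rep(1, 50), rnorm(50), max_lag = 3)
  expect_true(all(is.na(ccf$r)))
})

test_that("aggregate_ccf reproduces hand-computed values", {
  ccf <- tibble::tibble(segment = 1L, lag = -2:2, r = rep(0.5, 5))
  expect_equal(aggregate_ccf(ccf, "noabs", "all", fisher_z = FALSE), 0.5)
  ccf2 <- tibble::tibble(segment = 1L, lag = -2:2, r = rep(-0.4, 5))
  expect_equal(aggregate_ccf(ccf2, "abs", "all", fisher_z = FALSE), 0.4)
  expect_equal(aggregate_ccf(ccf2, "noabs", "all", fisher_z = FALSE), -0.4)
  # segments weighted equally regardless of defined-lag counts
  ccf3 <- tibble::tibble(
    segment = rep(1:2, each = 5), lag = rep(-2:2, 2),
    r = c(rep(0.2, 5), rep(0.6, 5))
  )
  expect_equal(aggregate_ccf(ccf3, "noabs", "all", fisher_z = FALSE), 0.4)
  # Fisher-z averaging: mean of atanh values
  expect_equal(aggregate_ccf(ccf3, "noabs", "all", fisher_z = TRUE),
               mean(c(atanh(0.2), atanh(0.6))))
})

test_that("aggregate_ccf lag subsets are strictly one-sided", {
  ccf <- tibble::tibble(segment = 1L, lag = -1:1, r = c(0.9, 0.1, -0.3))
  expect_equal(aggregate_ccf(ccf, "noabs", "negative", fisher_z = FALSE),
               0.9)
  expect_equal(aggregate_ccf(ccf, "noabs", "positive", fisher_z = FALSE),
               -0.3)
  # NA correlations are dropped, not imputed
  ccf$r[1] <- NA
  expect_error(
    aggregate_ccf(ccf[1, ], "noabs", "negative", fisher_z = FALSE),
    class = "dyadsync_undefined_aggregate"
  )
})

test_that("abs and noabs aggregates coincide when all correlations are positive", {
  set.seed(9)
  ccf <- tibble::tibble(segment = rep(1:3, each = 7),
                        lag = rep(-3:3, 3),
                        r = runif(21, 0.05, 0.9))
  expect_equal(aggregate_ccf(ccf, "abs", "all", fisher_z = TRUE),
               aggregate_ccf(ccf, "noabs", "all", fisher_z = TRUE),
               tolerance = 1e-12)
})

test_that("all-pairs surrogates enumerate every ordered mispairing", {
  # With m segments the cyclic scheme yields m - 1 surrogate sessions of m
  # mispairings each: all m * (m - 1) ordered pairs (i, j), i != j.
  data <- toy_dyad(120, seed = 3)  # 4 segments
  seg <- segment_dyad(data$patient, data$therapist, fs = 20)
  pd <- suppressWarnings(
    surrogate_distribution(seg, sync_config(), fs = 20, mode = "noabs")
  )
  expect_s3_class(pd, "pseudo_dist")
  expect_identical(pd$n_surrogates, seg$n_segments - 1L)
  expect_equal(pd$mean, mean(pd$values))
  expect_equal(pd$sd, stats::sd(pd$values))
})

test_that("all-pairs surrogates are deterministic; random shuffles are seeded", {
  data <- toy_dyad(180, seed = 4)
  seg <- segment_dyad(data$patient, data$therapist, fs = 20)
  a <- suppressWarnings(surrogate_distribution(seg, sync_config(), fs = 20))
  b <- suppressWarnings(surrogate_distribution(seg, sync_config(), fs = 20))
  expect_identical(a$values, b$values)

  cfg_r <- sync_config(surrogate_scheme = "random-shuffles",
                       n_shuffles = 40L, seed = 99L)
  r1 <- surrogate_distribution(seg, cfg_r, fs = 20)
  r2 <- surrogate_distribution(seg, cfg_r, fs = 20)
  expect_identical(r1$values, r2$values)
  expect_identical(r1$n_surrogates, 40L)
  # and they only use true mispairings, so they estimate the same null
  expect_lt(abs(r1$mean - a$mean), 5 * a$sd)
})

test_that("identical segments give a degenerate surrogate null", {
  base <- sin(seq(0, 2 * pi, length.out = 600))
  seg <- list(patient = matrix(rep(base, 3), ncol = 3),
              therapist = matrix(rep(rev(base), 3), ncol = 3),
              n_segments = 3L, n_dropped = 0L)
  expect_error(
    suppressWarnings(surrogate_distribution(seg, sync_config(), fs = 20)),
    class = "dyadsync_degenerate_null"
  )
})

test_that("fewer than 30 surrogates triggers a warning, not an error", {
  data <- toy_dyad(120, seed = 5)
  seg <- segment_dyad(data$patient, data$therapist, fs = 20)
  expect_warning(surrogate_distribution(seg, sync_config(), fs = 20),
                 class = "dyadsync_few_surrogates")
})

test_that("effect_size is (real - pseudo mean) / pseudo sd", {
  pd <- structure(list(values = c(0, 0.2), mean = 0.1, sd = 0.2,
                       n_surrogates = 2L),
                  class = "pseudo_dist")
  expect_equal(effect_size(0.5, pd), 2)
  expect_equal(effect_size(0.1, pd), 0)
  expect_error(effect_size(0.5, list(mean = 0, sd = 1)),
               class = "dyadsync_invalid_input")
})

test_that("compute_synchrony matches the brute-force oracle", {
  for (use_z in c(FALSE, TRUE)) {
    data <- toy_dyad(90, seed = 21)  # 3 segments
    cfg <- sync_config(fisher_z = use_z)
    got <- quiet_sync(data, fs = 20, cfg = cfg)
    ref <- oracle_synchrony(data$patient, data$therapist, fs = 20,
                            use_fisher_z = use_z)
    expect_equal(got$n_segments, ref$n_segments)
    for (v in c("abs", "noabs", "abs_pt_lead", "noabs_pt_lead",
                "abs_th_lead", "noabs_th_lead")) {
      expect_equal(got[[paste0("real_", v)]], ref[[paste0("real_", v)]],
                   tolerance = 1e-10)
      expect_equal(got[[paste0("pseudo_mean_", v)]],
                   ref[[paste0("pseudo_mean_", v)]], tolerance = 1e-10)
      expect_equal(got[[paste0("pseudo_sd_", v)]],
                   ref[[paste0("pseudo_sd_", v)]], tolerance = 1e-10)
      expect_equal(got[[paste0("es_", v)]], ref[[paste0("es_", v)]],
                   tolerance = 1e-10)
    }
  }
})

test_that("negating one channel flips signed synchrony and preserves es_abs", {
  data <- toy_dyad(150, seed = 22)
  flipped <- data
  flipped$therapist <- -flipped$therapist
  a <- quiet_sync(data, fs = 20)
  b <- quiet_sync(flipped, fs = 20)
  # Pearson r is exactly antisymmetric under negation; atanh is odd, so the
  # signed aggregates negate exactly and the absolute ones are unchanged.
  expect_equal(b$real_noabs, -a$real_noabs, tolerance = 1e-12)
  expect_equal(b$es_noabs, -a$es_noabs, tolerance = 1e-10)
  expect_equal(b$real_abs, a$real_abs, tolerance = 1e-12)
  expect_equal(b$es_abs, a$es_abs, tolerance = 1e-10)
  expect_equal(b$es_noabs_pt_lead, -a$es_noabs_pt_lead, tolerance = 1e-10)
})

test_that("time-reversing both channels swaps the leading variants", {
  data <- toy_dyad(150, seed = 23)  # exact multiple of one segment
  rev_data <- tibble::tibble(patient = rev(data$patient),
                             therapist = rev(data$therapist))
  a <- quiet_sync(data, fs = 20)
  b <- quiet_sync(rev_data, fs = 20)
  expect_equal(b$real_abs_pt_lead, a$real_abs_th_lead, tolerance = 1e-12)
  expect_equal(b$real_abs_th_lead, a$real_abs_pt_lead, tolerance = 1e-12)
  expect_equal(b$es_noabs_pt_lead, a$es_noabs_th_lead, tolerance = 1e-10)
  expect_equal(b$es_noabs_th_lead, a$es_noabs_pt_lead, tolerance = 1e-10)
  expect_equal(b$es_abs, a$es_abs, tolerance = 1e-10)
})

test_that("compute_synchrony is bit-reproducible", {
  data <- toy_dyad(150, seed = 24)
  a <- quiet_sync(data, fs = 20)
  b <- quiet_sync(data, fs = 20)
  expect_identical(a, b)
})

test_that("sync_config validates its arguments", {
  expect_error(sync_config(segment_seconds = -1),
               class = "dyadsync_invalid_parameter")
  expect_error(sync_config(surrogate_scheme = "bogus"))
  expect_error(
    sync_config(surrogate_scheme = "random-shuffles", n_shuffles = 10L),
    class = "dyadsync_invalid_parameter"
  )
  # segments must be able to hold the full lag range
  expect_error(
    quiet_sync(toy_dyad(90, seed = 1), fs = 20,
               cfg = sync_config(segment_seconds = 5, max_lag_seconds = 5)),
    class = "dyadsync_invalid_parameter"
  )
})
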