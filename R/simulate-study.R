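#' Score-generation model for simulated studies
#'
#' Coefficients linking each simulated session's ground-truth coupling
#' strength to the questionnaire scores the stats layer consumes. Every
#' score is generated directly on the subscale scale as
#' `therapy baseline + coef * (session coupling probability - template
#' coupling probability) + noise`, then clipped to the instrument range
#' (WAI subscales 1-5, SEQ 1-7, OQ-10 subscales 0-20).
#'
#' @param coef Named numeric vector of coupling coefficients; names must
#'   be score columns among `wai_{bond,goal,task}_{pt,th}`,
#'   `seq_{depth,smoothness,positivity,arousal}_{pt,th}`,
#'   `oq10_{wellness,distress}`. Unnamed scores get coefficient 0.
#' @param baseline_sd SD of the per-therapy random baseline of each
#'   score (rater/course effects, default 0.5).
#' @param noise_sd SD of the per-session score noise (default 0.5).
#' @param outcome_improvement Mean pre-to-post change of each OQ-45
#'   subscale (default -12; negative = symptomatic improvement).
#' @param outcome_noise_sd SD of pre-post change noise (default 6).
#' @param outcome_coef Named numeric vector linking a course's mean
#'   coupling probability to its OQ-45 subscale change
#'   (`distress`, `social_role`, `interpersonal`); default all 0.
#' @return An object of class `score_model`.
#' @export
score_model <- function(coef = c(), baseline_sd = 0.5, noise_sd = 0.5,
                        outcome_improvement = -12, outcome_noise_sd = 6,
                        outcome_coef = c()) {
  known <- score_columns()
  bad <- setdiff(names(coef), known)
  if (length(bad) > 0L) {
    stop_dyadsync(paste0("Unknown score column(s): ",
                         paste(bad, collapse = ", ")),
                  "dyadsync_invalid_parameter")
  }
  bad_out <- setdiff(names(outcome_coef),
                     c("distress", "social_role", "interpersonal"))
  if (length(bad_out) > 0L) {
    stop_dyadsync(paste0("Unknown outcome subscale(s): ",
                         paste(bad_out, collapse = ", ")),
                  "dyadsync_invalid_parameter")
  }
  full <- setNames(numeric(length(known)), known)
  full[names(coef)] <- coef
  full_out <- c(distress = 0, social_role = 0, interpersonal = 0)
  full_out[names(outcome_coef)] <- outcome_coef
  structure(
    list(coef = full, baseline_sd = baseline_sd, noise_sd = noise_sd,
         outcome_improvement = outcome_improvement,
         outcome_noise_sd = outcome_noise_sd, outcome_coef = full_out),
    class = "score_model"
  )
}

score_columns <- function() {
  c(paste0("wai_", rep(c("bond", "goal", "task"), each = 2),
           c("_pt", "_th")),
    paste0("seq_", rep(c("depth", "smoothness", "positivity", "arousal"),
                       each = 2), c("_pt", "_th")),
    paste0("oq10_", c("wellness", "distress")))
}

score_range <- function(column) {
  if (startsWith(column, "wai_")) return(c(1, 5))
  if (startsWith(column, "seq_")) return(c(1, 7))
  c(0, 20)
}

score_midpoint <- function(column) mean(score_range(column))

#' Simulate a whole dyadic psychotherapy study with known ground truth
#'
#' Generates a study in the design of the target setting: `n_therapies`
#' therapy courses of up to `sessions_per_therapy` sessions (a fraction
#' terminates early), one simulated dyadic EDA session each, per-session
#' questionnaire scores generated from the ground-truth coupling via a
#' [score_model()], and per-therapy pre/post outcome subscales (with
#' `n_missing_post` courses lacking the post measurement). Session
#' coupling probabilities vary around the template's value on the logit
#' scale with a per-therapy random effect, so courses differ in their
#' typical synchrony. With `analyze = TRUE` every session is run through
#' [compute_synchrony()] and the per-session effect sizes are returned
#' ready for the stats layer.
#'
#' @param n_therapies Number of therapy courses (default 21).
#' @param sessions_per_therapy Protocol session count (default 16).
#' @param cfg A [sim_config()] template; its `seed` is ignored
#'   (per-session seeds are derived from `seed`).
#' @param model A [score_model()].
#' @param sync_cfg A [sync_config()] used when `analyze = TRUE`.
#' @param early_fraction Fraction of therapies that terminate early
#'   (default 0.4).
#' @param early_range Inclusive range of session counts for
#'   early-terminating therapies (default `c(8, 15)`).
#' @param n_missing_post Number of therapies without a post outcome
#'   measurement (default 2).
#' @param therapy_effect_sd,session_effect_sd SDs of the logit-scale
#'   therapy and session perturbations of the coupling probability
#'   (defaults 0.5 and 0.75).
#' @param analyze Compute per-session synchrony effect sizes? Default
#'   `TRUE`.
#' @param keep_signals Keep the raw signal tibbles in the result
#'   (memory-heavy for long studies)? Default `FALSE`.
#' @param seed Integer seed (required); identical arguments and seed
#'   reproduce the study bit-for-bit.
#' @return A list of class `dyad_study` with elements `sessions`
#'   (per-session ground truth: ids, seed, assigned and realized
#'   coupling, leader, lag), `scores`, `outcomes`, `synchrony` (if
#'   `analyze`), `excluded` (sessions skipped for a degenerate surrogate
#'   null), `signals` (if `keep_signals`) and `model`/`cfg` echoes.
#' @export
simulate_study <- function(n_therapies = 21L, sessions_per_therapy = 16L,
                           cfg = sim_config(), model = score_model(),
                           sync_cfg = sync_config(),
                           early_fraction = 0.4,
                           early_range = c(8L, 15L),
                           n_missing_post = 2L,
                           therapy_effect_sd = 0.5,
                           session_effect_sd = 0.75,
                           analyze = TRUE, keep_signals = FALSE,
                           seed) {
  check_number(n_therapies, "n_therapies", lower = 2)
  check_number(sessions_per_therapy, "sessions_per_therapy", lower = 1)
  check_number(early_fraction, "early_fraction", lower = 0, upper = 1)
  if (missing(seed)) {
    stop_dyadsync("`seed` is required.", "dyadsync_invalid_parameter")
  }
  if (!inherits(model, "score_model")) {
    stop_dyadsync("`model` must be a `score_model`.",
                  "dyadsync_invalid_input")
  }

  plan <- withr::with_seed(as.integer(seed), {
    n_therapies <- as.integer(n_therapies)
    lengths <- ifelse(
      runif(n_therapies) < early_fraction,
      sample(seq.int(early_range[1], early_range[2]), n_therapies,
             replace = TRUE),
      as.integer(sessions_per_therapy)
    )
    # early termination can only shorten a course, never extend it
    lengths <- pmin(lengths, as.integer(sessions_per_therapy))
    therapy_ids <- sprintf("T%02d", seq_len(n_therapies))
    u_therapy <- rnorm(n_therapies, 0, therapy_effect_sd)

    sessions <- purrr::map_dfr(seq_len(n_therapies), function(i) {
      k <- lengths[i]
      e <- rnorm(k, 0, session_effect_sd)
      prob <- stats::plogis(stats::qlogis(
        pmin(pmax(cfg$coupling_prob, 1e-3), 1 - 1e-3)
      ) + u_therapy[i] + e)
      tibble(
        therapy_id = therapy_ids[i],
        session_id = sprintf("S%02d", seq_len(k)),
        session_seed = sample.int(.Machine$integer.max - 1L, k),
        coupling_prob = prob
      )
    })

    missing_post <- sample(therapy_ids, min(n_missing_post, n_therapies))

    # Per-therapy score baselines, one per score column.
    baselines <- vapply(score_columns(), function(col) {
      score_midpoint(col) + rnorm(n_therapies, 0, model$baseline_sd)
    }, numeric(n_therapies))
    rownames(baselines) <- therapy_ids

    scores <- sessions[c("therapy_id", "session_id")]
    dev <- sessions$coupling_prob - cfg$coupling_prob
    for (col in score_columns()) {
      rng <- score_range(col)
      raw <- baselines[sessions$therapy_id, col] +
        model$coef[[col]] * dev +
        rnorm(nrow(sessions), 0, model$noise_sd)
      scores[[col]] <- pmin(pmax(raw, rng[1]), rng[2])
    }

    mean_coupling <- sessions |>
      dplyr::group_by(.data$therapy_id) |>
      dplyr::summarise(mc = mean(.data$coupling_prob), .groups = "drop")
    out_sub <- c("distress", "social_role", "interpersonal")
    pre_mid <- c(distress = 50, social_role = 18, interpersonal = 22)
    outcomes <- tibble(therapy_id = therapy_ids)
    for (s in out_sub) {
      pre <- pre_mid[[s]] + rnorm(n_therapies, 0, 8)
      change <- model$outcome_improvement +
        model$outcome_coef[[s]] *
          (mean_coupling$mc - cfg$coupling_prob) +
        rnorm(n_therapies, 0, model$outcome_noise_sd)
      post <- pre + change
      post[therapy_ids %in% missing_post] <- NA_real_
      outcomes[[paste0(s, "_pre")]] <- pmax(pre, 0)
      outcomes[[paste0(s, "_post")]] <- pmax(post, 0)
    }

    list(sessions = sessions, scores = scores, outcomes = outcomes)
  })

  sessions <- plan$sessions
  signals <- if (keep_signals) vector("list", nrow(sessions)) else NULL
  sync_rows <- list()
  excluded <- list()
  realized <- numeric(nrow(sessions))

  for (r in seq_len(nrow(sessions))) {
    scfg <- cfg
    scfg$coupling_prob <- sessions$coupling_prob[r]
    scfg$seed <- sessions$session_seed[r]
    sim <- simulate_dyad(scfg, therapy_id = sessions$therapy_id[r],
                         session_id = sessions$session_id[r])
    realized[r] <- sim$truth$realized_coupling
    if (keep_signals) signals[[r]] <- sim$data
    if (analyze) {
      res <- withCallingHandlers(
        tryCatch(
          compute_synchrony(sim$data, fs = cfg$fs, cfg = sync_cfg,
                            therapy_id = sessions$therapy_id[r],
                            session_id = sessions$session_id[r]),
          dyadsync_degenerate_null = function(e) e
        ),
        dyadsync_few_surrogates = function(w) {
          invokeRestart("muffleWarning")
        }
      )
      if (inherits(res, "condition")) {
        excluded[[length(excluded) + 1L]] <- tibble(
          therapy_id = sessions$therapy_id[r],
          session_id = sessions$session_id[r],
          reason = "degenerate_null"
        )
      } else {
        sync_rows[[length(sync_rows) + 1L]] <- res
      }
    }
  }
  sessions$realized_coupling <- realized
  sessions$leader <- cfg$leader
  sessions$lead_lag_seconds <- cfg$lead_lag_seconds
  sessions$coupling_gain <- cfg$coupling_gain

  structure(
    list(
      sessions = sessions,
      scores = plan$scores,
      outcomes = plan$outcomes,
      synchrony = if (analyze) dplyr::bind_rows(sync_rows) else NULL,
      excluded = if (length(excluded) > 0L) dplyr::bind_rows(excluded)
        else tibble(therapy_id = character(), session_id = character(),
                    reason = character()),
      signals = signals,
      model = model,
      cfg = cfg,
      sync_cfg = sync_cfg,
      seed = as.integer(seed)
    ),
    class = "dyad_study"
  )
}

#' @export
print.dyad_study <- function(x, ...) {
  cat(sprintf(
    "<dyad_study> %d sessions in %d therapies (seed %d)%s\n",
    nrow(x$sessions), dplyr::n_distinct(x$sessions$therapy_id), x$seed,
    if (!is.null(x$synchrony)) sprintf("; %d analyzed, %d excluded",
                                       nrow(x$synchrony),
                                       nrow(x$excluded)) else ""
  ))
  invisible(x)
}
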