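#' Read and validate a study manifest
#'
#' The manifest is a YAML file mapping therapy ids to their metadata and
#' session signal files:
#' ```yaml
#' therapies:
#'   T01:
#'     patient_id: P01
#'     therapist_id: TH1
#'     diagnosis: MDD
#'     sessions:
#'       - session_id: S01
#'         patient_file: T01_S01_patient.csv
#'         therapist_file: T01_S01_therapist.csv
#' ```
#' File paths are resolved relative to the manifest's directory; every
#' referenced file must exist and session ids must be unique within a
#' therapy.
#'
#' @param path Manifest YAML path.
#' @return A tibble with one row per session: `therapy_id`,
#'   `patient_id`, `therapist_id`, `diagnosis`, `session_id`,
#'   `patient_file`, `therapist_file` (absolute paths).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_dyadsync(sprintf("Manifest not found: %s", path),
                  "dyadsync_parse_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$therapies) || length(raw$therapies) == 0L) {
    stop_dyadsync("Manifest lists no therapies.", "dyadsync_no_sessions")
  }
  base <- dirname(normalizePath(path))
  rows <- purrr::imap_dfr(raw$therapies, function(th, tid) {
    if (is.null(th$sessions) || length(th$sessions) == 0L) {
      stop_dyadsync(sprintf("Therapy %s lists no sessions.", tid),
                    "dyadsync_no_sessions")
    }
    purrr::map_dfr(th$sessions, function(s) {
      tibble(
        therapy_id = tid,
        patient_id = th$patient_id %||% NA_character_,
        therapist_id = th$therapist_id %||% NA_character_,
        diagnosis = th$diagnosis %||% NA_character_,
        session_id = s$session_id,
        patient_file = file.path(base, s$patient_file),
        therapist_file = file.path(base, s$therapist_file)
      )
    })
  })
  dup <- rows |>
    dplyr::count(.data$therapy_id, .data$session_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop_dyadsync("Duplicate session ids within a therapy.",
                  "dyadsync_parse_error")
  }
  missing_files <- c(rows$patient_file, rows$therapist_file)
  missing_files <- missing_files[!file.exists(missing_files)]
  if (length(missing_files) > 0L) {
    stop_dyadsync(paste0("Missing signal file(s): ",
                         paste(basename(missing_files), collapse = ", ")),
                  "dyadsync_parse_error")
  }
  rows
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    preprocess = list(enabled = FALSE, target_fs = 20, cutoff = 1,
                      artifact_window = 20L, artifact_percentile = 0.99,
                      artifact_floor = 0.01),
    synchrony = list(segment_seconds = 30, max_lag_seconds = 5,
                     fisher_z = TRUE, surrogate_scheme = "all-pairs",
                     n_shuffles = 100L),
    stats = list(scores_file = NULL, outcomes_file = NULL,
                 wai_predictors = NULL, seq_predictors = NULL,
                 oq10_predictors = NULL)
  )
}

#' Read and validate a pipeline configuration
#'
#' YAML with optional sections `preprocess`, `synchrony`, `stats` and a
#' top-level `seed`; omitted keys take package defaults and unknown keys
#' are rejected (a typo must never silently fall back to a default).
#'
#' @param path Config YAML path, or `NULL` for all defaults.
#' @return A validated config list.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- pipeline_defaults()
  if (is.null(path)) return(defaults)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0L) {
    stop_dyadsync(paste0("Unknown config key(s): ",
                         paste(unknown, collapse = ", ")),
                  "dyadsync_parse_error")
  }
  for (section in c("preprocess", "synchrony", "stats")) {
    if (is.null(raw[[section]])) next
    bad <- setdiff(names(raw[[section]]), names(defaults[[section]]))
    if (length(bad) > 0L) {
      stop_dyadsync(sprintf("Unknown key(s) in `%s`: %s", section,
                            paste(bad, collapse = ", ")),
                    "dyadsync_parse_error")
    }
    defaults[[section]][names(raw[[section]])] <- raw[[section]]
  }
  if (!is.null(raw$seed)) defaults$seed <- as.integer(raw$seed)
  defaults
}

#' Run the full analysis pipeline over a study
#'
#' Ties the stages together: per session, the two signal files are read,
#' optionally preprocessed (raw recordings), and run through
#' [compute_synchrony()]; the per-session results, summary table and —
#' when score/outcome files are configured — the mixed-model and
#' pre/post regression reports are written to `out_dir` as CSVs. Every
#' output directory gets a `provenance.yaml` recording the seed and a
#' hash of the configuration, and a `log.csv` recording, per session,
#' the segment count or the reason it was skipped; sessions are never
#' dropped silently. Identical manifest, config and seed produce
#' byte-identical result CSVs.
#'
#' @param manifest A manifest tibble from [read_manifest()] (or a path
#'   to a manifest YAML).
#' @param config A config list from [read_pipeline_config()] (or a path
#'   to a config YAML, or `NULL` for defaults).
#' @param out_dir Output directory, created if needed.
#' @return The per-session synchrony results tibble, invisibly; all
#'   reports are on disk in `out_dir`.
#' @export
run_pipeline <- function(manifest, config = NULL, out_dir) {
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- read_manifest(manifest)
  }
  if (is.null(config) || is.character(config)) {
    config <- read_pipeline_config(config)
  }
  if (!is.data.frame(manifest) || nrow(manifest) == 0L) {
    stop_dyadsync("Manifest contains no sessions.", "dyadsync_no_sessions")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sync_cfg <- sync_config(
    segment_seconds = config$synchrony$segment_seconds,
    max_lag_seconds = config$synchrony$max_lag_seconds,
    fisher_z = config$synchrony$fisher_z,
    surrogate_scheme = config$synchrony$surrogate_scheme,
    n_shuffles = config$synchrony$n_shuffles,
    seed = config$seed
  )

  results <- list()
  log_rows <- list()
  for (r in seq_len(nrow(manifest))) {
    tid <- manifest$therapy_id[r]
    sid <- manifest$session_id[r]
    row <- tryCatch({
      pt <- read_session_csv(manifest$patient_file[r])
      th <- read_session_csv(manifest$therapist_file[r])
      fs_pt <- attr(pt, "fs")
      fs_th <- attr(th, "fs")
      if (fs_pt != fs_th) {
        stop_dyadsync(sprintf("%s/%s: channel sampling rates differ.",
                              tid, sid),
                      "dyadsync_invalid_input")
      }
      pt_v <- pt$eda
      th_v <- th$eda
      fs <- fs_pt
      n_common <- min(length(pt_v), length(th_v))
      pt_v <- pt_v[seq_len(n_common)]
      th_v <- th_v[seq_len(n_common)]
      artifact_pct <- NA_real_
      if (isTRUE(config$preprocess$enabled)) {
        pp <- config$preprocess
        clean_one <- function(x) {
          mask <- detect_artifacts(x, window = pp$artifact_window,
                                   percentile = pp$artifact_percentile,
                                   floor = pp$artifact_floor)
          x <- repair_artifacts(x, mask)
          x <- lowpass_filter(x, fs = fs, cutoff = pp$cutoff)
          list(values = downsample_signal(x, fs = fs,
                                          target_fs = pp$target_fs),
               flagged = length(mask$flagged) / length(x))
        }
        cp <- clean_one(pt_v)
        ct <- clean_one(th_v)
        artifact_pct <- 100 * (cp$flagged + ct$flagged) / 2
        pt_v <- cp$values
        th_v <- ct$values
        fs <- pp$target_fs
      }
      res <- withCallingHandlers(
        compute_synchrony(
          tibble(patient = pt_v, therapist = th_v),
          fs = fs, cfg = sync_cfg, therapy_id = tid, session_id = sid
        ),
        dyadsync_few_surrogates = function(w) invokeRestart("muffleWarning")
      )
      log_rows[[length(log_rows) + 1L]] <- tibble(
        therapy_id = tid, session_id = sid, status = "ok",
        n_segments = res$n_segments, artifact_pct = artifact_pct,
        reason = NA_character_
      )
      res
    }, dyadsync_error = function(e) {
      reason <- setdiff(class(e), c("dyadsync_error", "rlang_error",
                                    "error", "condition"))[1]
      log_rows[[length(log_rows) + 1L]] <<- tibble(
        therapy_id = tid, session_id = sid, status = "skipped",
        n_segments = NA_integer_, artifact_pct = NA_real_,
        reason = reason
      )
      NULL
    })
    if (!is.null(row)) results[[length(results) + 1L]] <- row
  }

  log_tbl <- dplyr::bind_rows(log_rows)
  readr::write_csv(log_tbl, file.path(out_dir, "log.csv"))
  yaml::write_yaml(
    list(seed = config$seed, config_hash = rlang::hash(config),
         n_sessions = nrow(manifest),
         n_analyzed = length(results)),
    file.path(out_dir, "provenance.yaml")
  )

  if (length(results) == 0L) {
    stop_dyadsync("No session could be analyzed; see log.csv.",
                  "dyadsync_no_sessions")
  }
  results <- dplyr::bind_rows(results)
  readr::write_csv(results, file.path(out_dir, "synchrony.csv"))
  readr::write_csv(summarize_synchrony(results),
                   file.path(out_dir, "summary.csv"))
  course <- per_course_means(results)
  readr::write_csv(course, file.path(out_dir, "course_means.csv"))

  st <- config$stats
  if (!is.null(st$scores_file)) {
    scores <- read_scores_csv(st$scores_file)
    merged <- dplyr::inner_join(results, scores,
                                by = c("therapy_id", "session_id"))
    model_specs <- list(
      wai = st$wai_predictors,
      seq = st$seq_predictors,
      oq10 = st$oq10_predictors
    )
    reports <- list()
    for (block in names(model_specs)) {
      preds <- model_specs[[block]]
      if (is.null(preds)) next
      for (dep in c("es_abs", "es_noabs", "es_abs_pt_lead",
                    "es_noabs_pt_lead")) {
        fit <- tryCatch(
          suppressWarnings(
            fit_random_intercept(merged, dep, unlist(preds))
          ),
          dyadsync_error = function(e) NULL
        )
        if (is.null(fit)) next
        reports[[length(reports) + 1L]] <- dplyr::bind_cols(
          tibble(block = block, response = dep),
          tidy(fit),
          glance(fit)[rep(1L, nrow(tidy(fit))),
                      c("n_obs", "random_intercept_pct",
                        "r2_conditional_pct")]
        )
      }
    }
    if (length(reports) > 0L) {
      readr::write_csv(dplyr::bind_rows(reports),
                       file.path(out_dir, "mixed_models.csv"))
    }
  }
  if (!is.null(st$outcomes_file)) {
    outcomes <- read_outcomes_csv(st$outcomes_file)
    fit <- tryCatch(
      prepost_outcome_regression(outcomes, course),
      dyadsync_error = function(e) NULL
    )
    if (!is.null(fit)) {
      readr::write_csv(tidy(fit), file.path(out_dir, "outcome_model.csv"))
      readr::write_csv(fit$change_tests,
                       file.path(out_dir, "outcome_changes.csv"))
    }
  }

  invisible(results)
}
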