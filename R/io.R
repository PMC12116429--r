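#' Read and write per-session EDA signal files
#'
#' Session signals travel as self-describing CSV text files: a block of
#' `# key: value` header lines declaring the sampling rate, role and
#' identifiers, followed by a single `eda` column of values in
#' microsiemens. The header prevents silent unit or rate mix-ups when
#' files move between tools.
#'
#' @param path File path.
#' @return `read_session_csv()` returns a tibble with one `eda` column
#'   and attributes `fs`, `role`, `session_id`, `therapy_id`;
#'   `write_session_csv()` returns `path` invisibly.
#' @export
read_session_csv <- function(path) {
  if (!file.exists(path)) {
    stop_dyadsync(sprintf("File not found: %s", path),
                  "dyadsync_parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  header_n <- 0L
  meta <- list()
  for (ln in lines) {
    if (!startsWith(ln, "#")) break
    header_n <- header_n + 1L
    kv <- sub("^#\\s*", "", ln)
    colon <- regexpr(":", kv, fixed = TRUE)
    if (colon > 0L) {
      key <- trimws(substr(kv, 1L, colon - 1L))
      meta[[key]] <- trimws(substr(kv, colon + 1L, nchar(kv)))
    }
  }
  required <- c("fs", "role", "session_id", "therapy_id")
  missing_keys <- setdiff(required, names(meta))
  if (length(missing_keys) > 0L) {
    stop_dyadsync(
      sprintf("%s: header lacks required field(s): %s", path,
              paste(missing_keys, collapse = ", ")),
      "dyadsync_parse_error"
    )
  }
  fs <- suppressWarnings(as.numeric(meta$fs))
  if (is.na(fs) || fs <= 0) {
    stop_dyadsync(sprintf("%s: invalid sampling rate `%s`.", path, meta$fs),
                  "dyadsync_parse_error")
  }

  if (header_n + 2L > length(lines)) {
    stop_dyadsync(sprintf("%s: no data rows after the header.", path),
                  "dyadsync_parse_error")
  }
  body <- lines[seq.int(header_n + 1L, length(lines))]
  if (length(body) < 2L || body[1] != "eda") {
    stop_dyadsync(sprintf("%s: expected an `eda` column after the header.",
                          path),
                  "dyadsync_parse_error")
  }
  values <- suppressWarnings(as.numeric(body[-1]))
  bad <- which(!is.finite(values))
  if (length(bad) > 0L) {
    stop_dyadsync(
      sprintf("%s: non-numeric or non-finite value at line %d.",
              path, header_n + 1L + bad[1]),
      "dyadsync_parse_error"
    )
  }
  out <- tibble(eda = values)
  attr(out, "fs") <- fs
  attr(out, "role") <- meta$role
  attr(out, "session_id") <- meta$session_id
  attr(out, "therapy_id") <- meta$therapy_id
  out
}

#' @rdname read_session_csv
#' @param values Numeric vector of samples (microsiemens).
#' @param fs Sampling rate in Hz.
#' @param role `"patient"` or `"therapist"`.
#' @param session_id,therapy_id Identifiers.
#' @export
write_session_csv <- function(path, values, fs, role, session_id,
                              therapy_id) {
  check_numeric_vector(values, "values")
  check_number(fs, "fs", lower = 1e-12)
  header <- c(
    "# dyadsync session signal",
    sprintf("# fs: %s", format(fs, scientific = FALSE)),
    sprintf("# role: %s", role),
    sprintf("# session_id: %s", session_id),
    sprintf("# therapy_id: %s", therapy_id)
  )
  writeLines(c(header, "eda", format(values, digits = 15, trim = TRUE,
                                     scientific = FALSE)),
             path)
  invisible(path)
}

#' Read per-session questionnaire scores
#'
#' One row per session: `therapy_id`, `session_id`, then any of the
#' score columns (WAI, SEQ, OQ-10 subscales). Missing scales are allowed
#' and propagate as `NA` (models drop incomplete sessions listwise).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_scores_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("therapy_id", "session_id") %in% names(df))) {
    stop_dyadsync(sprintf("%s: needs `therapy_id` and `session_id` columns.",
                          path),
                  "dyadsync_parse_error")
  }
  df
}

#' Read per-therapy pre/post outcome subscales
#'
#' One row per therapy: `therapy_id` plus `<subscale>_pre` and
#' `<subscale>_post` columns. A missing post measurement is `NA`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_outcomes_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"therapy_id" %in% names(df)) {
    stop_dyadsync(sprintf("%s: needs a `therapy_id` column.", path),
                  "dyadsync_parse_error")
  }
  df
}

#' Write a simulated study to the pipeline's interchange formats
#'
#' Emits the session signal CSVs, the scores CSV, the outcomes CSV, a
#' ground-truth CSV and a manifest referencing them — exactly the inputs
#' [run_pipeline()] consumes, so a simulated study can be replayed
#' through the same path as real recordings. Requires the study to have
#' been simulated with `keep_signals = TRUE`.
#'
#' @param study A [`dyad_study`][simulate_study].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!inherits(study, "dyad_study")) {
    stop_dyadsync("`study` must be a `dyad_study`.",
                  "dyadsync_invalid_input")
  }
  if (is.null(study$signals)) {
    stop_dyadsync("Study was simulated with `keep_signals = FALSE`.",
                  "dyadsync_invalid_input")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- study$sessions
  manifest <- list(therapies = list())
  for (tid in unique(sessions$therapy_id)) {
    rows <- which(sessions$therapy_id == tid)
    sess_list <- lapply(rows, function(r) {
      sid <- sessions$session_id[r]
      pfile <- sprintf("%s_%s_patient.csv", tid, sid)
      tfile <- sprintf("%s_%s_therapist.csv", tid, sid)
      sig <- study$signals[[r]]
      write_session_csv(file.path(dir, pfile), sig$patient, study$cfg$fs,
                        "patient", sid, tid)
      write_session_csv(file.path(dir, tfile), sig$therapist,
                        study$cfg$fs, "therapist", sid, tid)
      list(session_id = sid, patient_file = pfile, therapist_file = tfile)
    })
    manifest$therapies[[tid]] <- list(
      patient_id = paste0("P_", tid),
      therapist_id = paste0("TH_", tid),
      diagnosis = "synthetic",
      sessions = sess_list
    )
  }
  readr::write_csv(study$scores, file.path(dir, "scores.csv"))
  readr::write_csv(study$outcomes, file.path(dir, "outcomes.csv"))
  readr::write_csv(sessions, file.path(dir, "ground_truth.csv"))
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}
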