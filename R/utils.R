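# Structured conditions used across the package. Every error raised by
# dyadsync carries the class "dyadsync_error" plus a specific subclass so
# callers (and the pipeline runner) can branch on the reason.
stop_dyadsync <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "dyadsync_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x) && allow_null) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop_dyadsync(
      sprintf("`%s` must be a single finite number in [%s, %s].",
              name, format(lower), format(upper)),
      "dyadsync_invalid_parameter"
    )
  }
  invisible(x)
}

check_numeric_vector <- function(x, name, min_length = 1L,
                                 finite = TRUE) {
  if (!is.numeric(x) || length(x) < min_length) {
    stop_dyadsync(
      sprintf("`%s` must be a numeric vector of length >= %d.",
              name, min_length),
      "dyadsync_invalid_input"
    )
  }
  if (finite && !all(is.finite(x))) {
    stop_dyadsync(sprintf("`%s` contains non-finite values.", name),
                  "dyadsync_invalid_input")
  }
  invisible(x)
}

# Fisher z with clamping so that |r| = 1 (identical segments) stays finite.
fisher_z <- function(r, clamp = 1 - 1e-12) {
  atanh(pmin(pmax(r, -clamp), clamp))
}
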