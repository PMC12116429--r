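#' Canonical bi-exponential skin-conductance response kernel
#'
#' `h(t) = exp(-t / tau1) - exp(-t / tau2)`, normalized to unit peak.
#' `tau1` is the (slower) recovery time constant and `tau2` the (faster)
#' rise constant; the peak occurs at
#' `t* = tau1 * tau2 / (tau1 - tau2) * log(tau1 / tau2)`.
#'
#' @param t Time in seconds, `t >= 0` (vectorized).
#' @param tau1 Recovery time constant in seconds; must exceed `tau2`.
#' @param tau2 Rise time constant in seconds; must be positive.
#' @return Kernel amplitude(s), peaking at 1.
#' @examples
#' scr_kernel(0, 2, 0.75)          # 0 at onset
#' t_star <- 2 * 0.5 / (2 - 0.5) * log(2 / 0.5)
#' scr_kernel(t_star, 2, 0.5)      # 1 at the peak
#' @export
scr_kernel <- function(t, tau1 = 2, tau2 = 0.75) {
  check_number(tau1, "tau1", lower = 1e-12)
  check_number(tau2, "tau2", lower = 1e-12)
  if (tau1 <= tau2) {
    stop_dyadsync("`tau1` must be greater than `tau2`.",
                  "dyadsync_invalid_parameter")
  }
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop_dyadsync("`t` must be finite and non-negative.",
                  "dyadsync_invalid_parameter")
  }
  t_star <- tau1 * tau2 / (tau1 - tau2) * log(tau1 / tau2)
  peak <- exp(-t_star / tau1) - exp(-t_star / tau2)
  (exp(-t / tau1) - exp(-t / tau2)) / peak
}

#' Configuration for the synthetic dyad generator
#'
#' Ground-truth parameters of one simulated dyadic EDA session. The
#' generator emulates the signal class of phasic skin conductance: each
#' person's series is a Poisson train of skin-conductance responses
#' (bi-exponential kernel, lognormal amplitudes) riding on a tonic level
#' with slow drift and sensor noise; cross-person coupling propagates a
#' controllable fraction of the leader's response events to the follower
#' with a controllable sign, gain and delay.
#'
#' @param fs Sampling rate in Hz (default 20; use 2000 to exercise the
#'   raw-signal preprocessing chain).
#' @param duration_seconds Session duration (default 3000 s, i.e. a
#'   50-min session).
#' @param event_rate Driver SCR events per minute per person (default 6).
#' @param coupling_prob Probability that a leader event propagates to the
#'   follower (0 = independent dyad).
#' @param coupling_gain Signed amplitude multiplier of propagated events;
#'   negative values produce anti-phase covariation (default 1).
#' @param lead_lag_seconds Delay from a leader event to its propagated
#'   copy in the follower (default 0).
#' @param leader `"patient"` or `"therapist"`.
#' @param scr_tau1,scr_tau2 SCR kernel time constants in seconds
#'   (defaults 2 and 0.75, canonical skin-conductance values).
#' @param amp_meanlog,amp_sdlog Lognormal event-amplitude parameters in
#'   log-microsiemens (defaults 0 and 0.4).
#' @param noise_sd Additive Gaussian sensor noise SD in microsiemens
#'   (default 0.02).
#' @param drift_amplitude,drift_period_seconds Slow sinusoidal tonic
#'   drift (default 0.3 uS amplitude, 600 s period, random phase).
#' @param tonic_offset Baseline conductance level in microsiemens
#'   (default 4).
#' @param artifact_count,artifact_magnitude Number and size (uS) of
#'   spike discontinuities injected per channel at recorded indices
#'   (default none).
#' @param seed Integer seed; required by [simulate_dyad()] for
#'   reproducibility.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fs = 20, duration_seconds = 3000, event_rate = 6,
                       coupling_prob = 0.5, coupling_gain = 1,
                       lead_lag_seconds = 0,
                       leader = c("patient", "therapist"),
                       scr_tau1 = 2, scr_tau2 = 0.75,
                       amp_meanlog = 0, amp_sdlog = 0.4,
                       noise_sd = 0.02, drift_amplitude = 0.3,
                       drift_period_seconds = 600, tonic_offset = 4,
                       artifact_count = 0L, artifact_magnitude = 5,
                       seed = NULL) {
  check_number(fs, "fs", lower = 1e-9)
  check_number(duration_seconds, "duration_seconds", lower = 1e-9)
  check_number(event_rate, "event_rate", lower = 0)
  check_number(coupling_prob, "coupling_prob", lower = 0, upper = 1)
  check_number(coupling_gain, "coupling_gain")
  check_number(lead_lag_seconds, "lead_lag_seconds", lower = 0)
  check_number(scr_tau1, "scr_tau1", lower = 1e-12)
  check_number(scr_tau2, "scr_tau2", lower = 1e-12)
  if (scr_tau1 <= scr_tau2) {
    stop_dyadsync("`scr_tau1` must be greater than `scr_tau2`.",
                  "dyadsync_invalid_parameter")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(drift_amplitude, "drift_amplitude", lower = 0)
  check_number(tonic_offset, "tonic_offset", lower = 0)
  check_number(artifact_count, "artifact_count", lower = 0)
  check_number(artifact_magnitude, "artifact_magnitude", lower = 0)
  structure(
    list(fs = fs, duration_seconds = duration_seconds,
         event_rate = event_rate, coupling_prob = coupling_prob,
         coupling_gain = coupling_gain,
         lead_lag_seconds = lead_lag_seconds,
         leader = match.arg(leader),
         scr_tau1 = scr_tau1, scr_tau2 = scr_tau2,
         amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog,
         noise_sd = noise_sd, drift_amplitude = drift_amplitude,
         drift_period_seconds = drift_period_seconds,
         tonic_offset = tonic_offset,
         artifact_count = as.integer(artifact_count),
         artifact_magnitude = artifact_magnitude,
         seed = seed),
    class = "sim_config"
  )
}

# Convolve an impulse train with the SCR kernel (causal).
scr_convolve <- function(impulses, cfg) {
  n <- length(impulses)
  kt <- seq(0, 20 * cfg$scr_tau1, by = 1 / cfg$fs)
  kern <- scr_kernel(kt, cfg$scr_tau1, cfg$scr_tau2)
  convolve(impulses, rev(kern), type = "open")[seq_len(n)]
}

#' Simulate one dyadic EDA session with known ground truth
#'
#' Generates patient and therapist phasic EDA series per the coupling
#' model described in [sim_config()]: the leader's SCR events arise from
#' a Poisson process; the follower has independent events of its own
#' plus, with probability `coupling_prob`, a copy of each leader event
#' delayed by `lead_lag_seconds` and scaled by the signed
#' `coupling_gain` (negative gain subtracts conductance, producing
#' anti-phase covariation). Both series add tonic offset, slow drift and
#' sensor noise; optional spike artifacts are injected at recorded
#' indices. Identical configuration and seed reproduce the output
#' bit-for-bit.
#'
#' @param cfg A [sim_config()] with a non-`NULL` `seed`.
#' @param therapy_id,session_id Optional identifiers carried along.
#' @return A list of class `dyad_sim` with `data` (tibble: `t` in
#'   seconds, `patient`, `therapist` in microsiemens), `fs`, the ids,
#'   and `truth` (leader, event times, realized propagated-event
#'   fraction, artifact indices, and the generating config).
#' @export
simulate_dyad <- function(cfg = sim_config(seed = 1),
                          therapy_id = NA_character_,
                          session_id = NA_character_) {
  if (!inherits(cfg, "sim_config")) {
    stop_dyadsync("`cfg` must be a `sim_config`.", "dyadsync_invalid_input")
  }
  if (is.null(cfg$seed)) {
    stop_dyadsync("`cfg$seed` is required for reproducible simulation.",
                  "dyadsync_invalid_parameter")
  }
  withr::with_seed(as.integer(cfg$seed), {
    n <- as.integer(round(cfg$duration_seconds * cfg$fs))
    tt <- (seq_len(n) - 1L) / cfg$fs

    draw_events <- function() {
      k <- rpois(1L, cfg$event_rate * cfg$duration_seconds / 60)
      list(times = sort(runif(k, 0, cfg$duration_seconds)),
           amps = rlnorm(k, cfg$amp_meanlog, cfg$amp_sdlog))
    }
    impulses_of <- function(times, amps) {
      imp <- numeric(n)
      idx <- pmin(pmax(floor(times * cfg$fs) + 1L, 1L), n)
      for (i in seq_along(idx)) imp[idx[i]] <- imp[idx[i]] + amps[i]
      imp
    }

    lead <- draw_events()
    foll_own <- draw_events()
    propagated <- runif(length(lead$times)) < cfg$coupling_prob
    prop_times <- lead$times[propagated] + cfg$lead_lag_seconds
    prop_amps <- lead$amps[propagated] * cfg$coupling_gain
    in_range <- prop_times < cfg$duration_seconds
    prop_times <- prop_times[in_range]
    prop_amps <- prop_amps[in_range]

    lead_phasic <- scr_convolve(impulses_of(lead$times, lead$amps), cfg)
    foll_phasic <- scr_convolve(
      impulses_of(c(foll_own$times, prop_times),
                  c(foll_own$amps, prop_amps)),
      cfg
    )

    person_series <- function(phasic) {
      phase <- runif(1, 0, 2 * pi)
      drift <- cfg$drift_amplitude *
        sin(2 * pi * tt / cfg$drift_period_seconds + phase)
      series <- cfg$tonic_offset + drift + phasic + rnorm(n, 0, cfg$noise_sd)
      art_idx <- integer(0)
      if (cfg$artifact_count > 0L) {
        art_idx <- sort(sample.int(n, cfg$artifact_count))
        series[art_idx] <- series[art_idx] + cfg$artifact_magnitude
      }
      list(series = series, artifacts = art_idx)
    }

    if (cfg$leader == "patient") {
      pt <- person_series(lead_phasic)
      th <- person_series(foll_phasic)
    } else {
      th <- person_series(lead_phasic)
      pt <- person_series(foll_phasic)
    }

    structure(
      list(
        data = tibble(t = tt, patient = pt$series, therapist = th$series),
        fs = cfg$fs,
        therapy_id = therapy_id,
        session_id = session_id,
        truth = list(
          leader = cfg$leader,
          leader_event_times = lead$times,
          propagated_event_times = prop_times,
          realized_coupling = if (length(lead$times) > 0) {
            length(prop_times) / length(lead$times)
          } else {
            NA_real_
          },
          coupling_prob = cfg$coupling_prob,
          coupling_gain = cfg$coupling_gain,
          lead_lag_seconds = cfg$lead_lag_seconds,
          patient_artifacts = pt$artifacts,
          therapist_artifacts = th$artifacts,
          config = cfg
        )
      ),
      class = "dyad_sim"
    )
  })
}

#' @export
print.dyad_sim <- function(x, ...) {
  cat(sprintf(
    "<dyad_sim> %g s at %g Hz; leader %s, coupling %g x %+g, lag %g s\n",
    x$truth$config$duration_seconds, x$fs, x$truth$leader,
    x$truth$coupling_prob, x$truth$coupling_gain,
    x$truth$lead_lag_seconds
  ))
  invisible(x)
}
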