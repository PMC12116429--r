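# Shared helpers for Monte-Carlo tests.

# compute_synchrony while muffling the expected small-surrogate-count
# warning (short test sessions have fewer than 30 cyclic rotations).
quiet_sync <- function(data, fs = 20, cfg = sync_config(), ...) {
  withCallingHandlers(
    compute_synchrony(data, fs = fs, cfg = cfg, ...),
    dyadsync_few_surrogates = function(w) invokeRestart("muffleWarning")
  )
}

# Simulate `n` independent sessions from one condition and return the
# per-session synchrony results, seeded deterministically from `seed0`.
mc_sessions <- function(n, seed0, cfg = sync_config(), ...) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    sim <- simulate_dyad(sim_config(..., seed = seed0 + i))
    quiet_sync(sim$data, fs = sim$fs, cfg = cfg,
               therapy_id = "T01", session_id = sprintf("S%03d", i))
  }))
}

# A smooth SCR-like dyad signal pair for exactness/oracle tests.
toy_dyad <- function(n_seconds, fs = 20, seed = 42, coupling_prob = 0.8) {
  sim <- simulate_dyad(sim_config(duration_seconds = n_seconds, fs = fs,
                                  coupling_prob = coupling_prob,
                                  seed = seed))
  sim$data
}
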