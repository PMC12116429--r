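---
title: "Surrogate synchrony for dyadic electrodermal recordings: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate synchrony for dyadic electrodermal recordings: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dyadsync)
```

## The problem

When two people interact, their autonomic arousal can covary: moments of
activation in one partner are echoed, within seconds, in the other.
`dyadsync` quantifies this *physiological synchrony* for dyads (the
motivating setting is patient-therapist pairs in psychotherapy) from
concurrent electrodermal activity (EDA) recordings, and provides the
statistical layer for relating per-session synchrony to session-level
ratings and course-level outcomes.

The central difficulty is that two smooth, autocorrelated signals will
correlate substantially even when the people are completely unrelated.
Any raw correlation therefore needs a null reference that preserves each
signal's own dynamics while destroying the real-time pairing. That is
the surrogate (pseudo-synchrony) approach implemented here.

## The synchrony measure

Each session's two aligned phasic EDA series (nominally 20 Hz) are cut
into consecutive non-overlapping segments of `segment_seconds` (default
30 s, i.e. 600 samples). Within each segment, Pearson cross-correlations
are computed at every integer-sample lag up to `max_lag_seconds`
(default ±5 s, i.e. ±100 samples), each over the overlapping
`N - |lag|` sample pairs, without padding. The sign convention is fixed:
**negative lags mean the patient's activity precedes the therapist's**
(patient-leading), positive lags the reverse. Lag 0 belongs only to the
"all lags" aggregate; the leading subsets are strictly one-sided.

Correlations are aggregated in two modes:

* `noabs` — signed mean; preserves polarity, so predominantly anti-phase
  sessions (high-with-low covariation) come out negative;
* `abs` — mean of absolute values; measures coupling strength
  regardless of phase.

By default correlations are Fisher-z transformed (`atanh`, with inputs
clamped to `1 - 1e-12` in magnitude so the transform never returns
infinity) before averaging, which makes the mean approximately unbiased
for averaged correlations; the aggregate is then lag-averaged within a
segment and segment-averaged across the session, with every segment
weighted equally and undefined (zero-variance) lags dropped rather than
imputed.

## The surrogate null and effect size

The null distribution is obtained by recomputing the same session
aggregate on deliberately *mispaired* segments of the same two signals.
With `m` segments, the default `all-pairs` scheme walks the `m - 1`
cyclic rotations of the therapist's segment sequence: rotation `k`
pairs patient segment `i` with therapist segment `i + k (mod m)`.
Together these rotations cover every ordered mispairing `(i, j)`,
`i != j`, exactly once, and each rotation yields one surrogate *session
aggregate* computed over `m` mispairings — structurally identical to
the real session value, which aggregates the `m` true pairings. This
matters: because each surrogate value is itself a session-level mean,
the surrogate spread estimates the sampling variability of the session
aggregate under the null, and the effect size

\[
ES = \frac{\text{real} - \text{mean(pseudo)}}{\text{SD(pseudo)}}
\]

is approximately standard normal for uncoupled dyads. (Pooling all
`m(m-1)` segment-level mispairing values into one distribution instead
would inflate the null SD by roughly `sqrt(m)` and make ES incomparable
across session lengths.) The alternative `random-shuffles` scheme draws
seeded fixed-point-free permutations of whole segment sequences; it
estimates the same null and is provided for sensitivity analyses.

Two consequences of this design are worth knowing. First, a session
needs at least 3 full segments: with 2 segments there is only one
mispairing rotation, so the null SD is undefined and the session is
rejected as degenerate. Second, with fewer than 30 surrogate values the
null SD is itself noisy; the package warns
(`dyadsync_few_surrogates`) but proceeds, since the study-scale default
(50-min sessions, 100 segments, 99 surrogates) is comfortably above
that.

Six effect sizes are reported per session:
`{abs, noabs} x {all lags, patient-leading, therapist-leading}`, each
contrasted against a surrogate null computed under the same mode and
lag subset.

```{r}
sim <- simulate_dyad(sim_config(duration_seconds = 600,
                                coupling_prob = 0.8, seed = 1))
res <- compute_synchrony(sim$data, fs = 20)
round(t(res[, c("es_abs", "es_noabs",
                "es_noabs_pt_lead", "es_noabs_th_lead")]), 2)
```

## Preprocessing raw recordings

Raw EDA (e.g. 2000 Hz research-grade recordings) passes through:

1. **Artifact detection** (`detect_artifacts()`): electrode artifacts
   appear as step discontinuities. The detector computes absolute
   first differences, takes their sliding-window *maxima* (window of 20
   samples), and sets the threshold to the 99th percentile of those
   window maxima, with an absolute floor of 0.01 µS. Using window
   maxima instead of raw-difference percentiles is deliberate: a plain
   99th percentile of all differences would flag ~1% of samples of any
   clean recording by construction, whereas the distribution of window
   maxima separates ordinary noise from genuine jumps. Flagged
   differences are expanded by half a window on each side to cover the
   artifact's flanks.
2. **Repair** (`repair_artifacts()`): flagged spans are replaced by
   linear interpolation from the nearest clean samples; a fully flagged
   recording raises an unrecoverable-signal error rather than returning
   an invented series.
3. **Low-pass** (`lowpass_filter()`): 4th-order Butterworth at 1 Hz,
   applied forward and backward (zero phase). Because plain
   forward-backward filtering distorts edges, the filter first removes
   the line through the endpoints, then odd-extends the signal by
   `12 * fs / cutoff` samples at each end before `filtfilt`, and adds
   the line back. This keeps constants exactly constant, preserves
   linearity to machine precision, and confines edge transients: on
   content far below the cutoff, refiltering reproduces the signal to
   better than 1e-6 except within ~2 s of the recording edges, where
   transients of order 1e-5 remain. The analysis is insensitive to this
   because sessions are minutes long.
4. **Decimation** (`downsample_signal()`): plain sample-picking (every
   `fs / target_fs`-th sample, integer factors only) down to 20 Hz,
   yielding exactly `floor(n / factor)` samples. No anti-alias stage is
   needed beyond the 1 Hz low-pass already applied.

`preprocess_eda()` chains these per recording over a grouped data
frame.

## The synthetic dyad generator

`simulate_dyad()` produces ground-truth-known sessions of the same
signal class the measure targets. Each person's phasic activity is a
Poisson train of skin-conductance responses (default 6 events/min)
convolved with the canonical bi-exponential SCR kernel
`h(t) = exp(-t/tau1) - exp(-t/tau2)` (defaults `tau1 = 2`,
`tau2 = 0.75` s, unit-peak normalized), with lognormal amplitudes,
riding on a 4 µS tonic level with slow sinusoidal drift (0.3 µS over a
600 s period, random phase) plus Gaussian sensor noise (0.02 µS).
Coupling is event-level: each leader event propagates to the follower
with probability `coupling_prob`, amplitude multiplier `coupling_gain`
(negative values produce anti-phase covariation) and delay
`lead_lag_seconds`. Defaults mirror the target study's conditions
(20 Hz analysis rate, 50-min sessions, `coupling_prob = 0.5`).

What the generator does *not* emulate: respiration and movement
confounds, nonstationary event rates within a session, amplitude
habituation, or shared-stimulus (third-variable) synchrony. It is a
recovery testbed for the estimator, not a physiological model.

`simulate_study()` scales this to a whole study in the reference
design: 21 therapy courses of up to 16 sessions (a fraction terminating
early), per-session coupling probabilities varying on the logit scale
with per-course random effects, per-session questionnaire scores (WAI,
SEQ, OQ-10) generated from ground-truth coupling via `score_model()`,
and per-course pre/post outcome subscales with missing posts.

## The statistics layer

* `summarize_synchrony()` builds the standard summary: session- and
  course-level one-sample t-tests of the effect sizes against zero, and
  the patient- vs therapist-leading paired comparison, also repeated
  after cluster-wise centering (`cluster_center()`, grand mean
  restored) to remove between-course variance.
* `fit_random_intercept()` fits `response ~ predictors +
  (1 | therapy_id)` by REML with Satterthwaite degrees of freedom,
  reporting the random-intercept share of variance and marginal /
  conditional R². `refit_significant()` implements the two-stage
  protocol of refitting with only the predictors significant in the
  full model.
* `prepost_outcome_regression()` regresses course-mean synchrony on
  pre-to-post outcome change scores (change = post − pre; negative =
  improvement), with degenerate change scores flagged and dropped.

## Reproducibility and numerical choices

* Every stochastic function requires an explicit seed; identical
  arguments reproduce results bit-for-bit, and `run_pipeline()` stamps
  outputs with the seed and a configuration hash.
* Fisher-z inputs are clamped at `1 - 1e-12`; correlations from the
  cross-product kernel are clamped to `[-1, 1]` against rounding.
* Monte-Carlo problem sizes used in the package's own acceptance tests
  (session counts, replicate counts, 600 s test sessions instead of
  the 3000 s default) are runtime-driven choices of the test suite,
  selected before inspecting outcomes; the generator defaults
  themselves are never tuned.

## Limitations

Effect sizes from sessions with few segments are noisy and
conservative-to-liberal depending on the surrogate count; the lag range
(±5 s) upper-bounds detectable lead-lag asymmetries; and synchrony here
is correlational — the package's leader/follower language describes
temporal precedence, not causation.
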