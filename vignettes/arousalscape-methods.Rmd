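---
title: "Detecting and typing spontaneous sleep arousals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and typing spontaneous sleep arousals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arousalscape)
```

## The problem

Spontaneous arousals — transient accelerations of the sleep EEG lasting a
few seconds — are usually read as markers of disturbed sleep, but they are
heterogeneous: some coincide with a sleep-stage transition (T+) and some do
not (T−); some are accompanied by a rise in submental muscle tone (M+) and
some are not (M−). The four resulting types (T+M+, T+M−, T−M+, T−M−) can
have different spectral signatures and different relationships to markers
of brain health such as cortical amyloid-β burden (in Centiloid units) and
cognitive performance. `arousalscape` implements the full analysis chain —
detection, typing, spectral profiling, per-subject fragmentation metrics,
and the association models — together with a synthetic
polysomnography/cohort generator that provides ground truth for every
stage.

## The detector

Detection operates on **1-second epochs** of per-channel band power,
computed as a Hann-tapered periodogram per epoch, summed over three bands:
lower-theta 3–7 Hz, broad-alpha, and beta 16–30 Hz. The sigma spindle
range 11–16 Hz must not contribute (spindles are not arousals), so by
default broad-alpha is truncated to 7–11 Hz rather than the nominal
7–13 Hz; the full 7–13 Hz band is available via
`detection_config(sigma_exclusion = FALSE)`. Band edges are inclusive on
the 1-Hz frequency grid that 1-s epochs induce.

Two thresholds act together, both within a single band (bands combine by
OR):

1. **Whole-night (fixed) threshold** — the epoch's power must strictly
   exceed the whole-night median of that band and channel.
2. **Local adaptive threshold** — it must strictly exceed **twice** the
   median over a 30-s window's EMG-quiet epochs plus the nearest ten quiet
   epochs on each side. EMG-active epochs (RMS of the ≥10 Hz high-passed
   EMG above twice a 60-s rolling-median baseline) are excluded so that
   muscle artifacts do not inflate the local background.

Runs of at least **3 consecutive** suprathreshold epochs on a channel
become candidate events; candidates overlapping across channels are merged
(arousals are spatially global; merging avoids double counting), events
whose onset epoch is scored wake are discarded, events closer than 10 s
are merged, and events longer than 15 s are flagged `awakening_candidate`
and excluded from arousal densities. The 10-s and 15-s values follow
standard scoring conventions and are configurable.

Strict inequalities make the degenerate constant-power recording yield
zero events, and because both thresholds are medians of the tested
quantity, the detector is exactly invariant to rescaling all EEG channels
by a positive constant.

Choices made where the scoring rule leaves latitude (all exposed in
`detection_config()`):

* the 3-epoch run must be on a single channel, with any band providing the
  evidence at each epoch;
* windows with no selectable quiet epoch fall back to the whole-night
  median with a warning;
* the EMG "tone increase" criterion (high-passed RMS vs. a rolling-median
  baseline, factor 2) is a declared stand-in for the reference scorer's
  unpublished rule.

## Typing

**Transition status** uses the half-epoch operationalization of "within
15 s of a stage change": T+ when the onset lies in the second half of an
epoch preceding a stage change, or in the first half of an epoch whose
stage differs from its predecessor. All intervals are half-open, epoch *k*
covers `[30k, 30k+30)`, and an onset exactly at mid-epoch belongs to the
second half; the transition is evaluated at onset only, the one
unambiguous time point of an event. **EMG status** is M+ when any 1-s
epoch strictly overlapping the event span is EMG-active. In REM sleep an
arousal requires a muscle-tone change by scoring definition, so REM
events classified M− are marked `rem_discarded` and excluded from density
counts (configurable).

## Spectral profiles

For each retained event the first **3 s** from onset are decomposed with
Morlet wavelets (7 cycles, 1-Hz steps at 0.5–29.5 Hz — 30 bins covering
0.5–30 Hz) on Fz. Power is corrected against the 500 ms before onset:
per-frequency baseline subtraction floored at zero is the default, with
divisive and z-score alternatives implemented, since the published
pipelines differ on this point. Per type, corrected power is averaged
across events, collapsed over time, summed into the reporting bands
(theta 4.5–7.5, alpha 8.5–11.5, beta 16.5–29.5 Hz, inclusive edges) and
normalized by the 0.5–30 Hz total. Shares are ratios of raw power, not of
dB values, and are invariant to amplitude rescaling. Types with no events
are absent rather than zero-filled.

## Fragmentation metrics

Total sleep time is 30 s per non-wake epoch. Hourly densities are counts
of retained events per hour of total sleep time, per type; the four type
densities sum to the total by construction. WASO counts wake epochs
strictly after sleep onset (first sleep epoch; a 3-consecutive-epoch
variant is available) and before the final sleep epoch — terminal wake is
excluded by default, as is conventional, and both choices are
configurable because operational definitions vary across labs. Awakenings
are maximal wake runs in the same span, counted at 30-s resolution, which
deliberately distinguishes them from the >15-s `awakening_candidate`
events flagged at the 1-s level by the detector.

## Association models

`build_composites()` z-scores each task across the cohort (sign-flipping
lower-is-better scores such as reaction times), sums within domain,
z-scores the sum, and z-scores the sum of domain composites for the
global score, so every composite has mean 0 and SD 1 exactly.

With one PSG night and one PET value per subject, the amyloid and
cognition models have a single observation per subject, so the subject
random intercept degenerates and `fit_abeta_model()` /
`fit_cognition_model()` are fixed-effects linear models: amyloid ~ T−M+
density + T+M− density + age + sex (education added for cognition), type
II F tests. A contrast on standardized slopes compares the two arousal
terms. The density model (`fit_density_model()`) has four rows per
subject and is a genuine mixed model: density ~ T × M × standardized
amyloid + age + sex + (1 | subject), and likewise the spectral model
rel_power ~ T × M × band + (1 | subject), with Tukey-adjusted post hoc
contrasts within the relevant factor cells.

Design choices:

* **Effect sizes.** For every fixed-effect F test with numerator df *q*
  and denominator df ν₂, the semipartial effect size is
  R²β = qF / (qF + ν₂); `r2_beta()` is the single implementation used
  everywhere.
* **Denominator dfs.** Satterthwaite is the default for mixed fits, with
  Kenward-Roger available (`ddf = "Kenward-Roger"`); at ~100 subjects the
  two agree closely, and the choice is recorded in the result object.
* **Response distribution.** Instead of an unreproducible scan of "all
  parametric distributions", a fixed candidate set (normal, log-normal,
  gamma) is scored by AIC; log-normal fits model the log response, and a
  gamma GLMM that fails to converge falls back, with a recorded note, to
  a normal LMM on `log1p(y)`. Responses containing non-positive values
  admit only the normal candidate.
* **Diagnostics.** Cook's distance with the conventional flag threshold
  of 1 is computed for the fixed-effects models; no observation is
  silently removed. No multiple-testing correction is applied across
  models; Tukey adjustment is used only within post hoc families.
* Sex enters as a two-level factor, education as years (continuous).

## The synthetic generator

`simulate_psg()` emulates what the detector actually sees — per-stage
band-power structure — rather than a biophysical EEG. The background is a
1-Hz-spaced harmonic comb (random phases drawn once per night) whose
per-stage amplitude envelopes follow a 1/f^slope decay plus Gaussian
oscillatory peaks (wake alpha, NREM theta, N2 sigma at 13 Hz, N3 delta),
interpolated over 30 s at stage borders, plus a white-noise floor and
per-channel gains over a shared comb (scalp derivations are strongly
correlated). Two properties of this construction are deliberate:

* **Exact spectra.** The per-stage band powers equal sum(A²)/2
  analytically, so the spectral-fidelity contract (median quiet-epoch
  band power within 10% of the configured spectrum) is testable without
  estimator noise.
* **Planted events are the only suprathreshold structure.** Per-epoch
  band power of a stochastic background fluctuates enough (chi-square
  with few degrees of freedom) that a median-ratio detector would fire on
  background alone; the deterministic comb keeps the quiet-night false
  positive floor at essentially zero, which is the intended study
  condition.

Planted arousals are phase-aligned amplifications of the background's own
in-band harmonics: multiplying each component in the detection band by
√boost scales that band's power by exactly `boost` in every second of the
event (incoherent injection would interfere with the background and could
cancel mid-event). Primary-band boost defaults to 8 (secondary 3) — the
source literature reports no arousal amplitude statistics, so these are
calibration choices of the generator. T−M+ events are beta-dominant and
T+M− theta-dominant by default, reproducing the qualitative spectral
contrast between types. M+ events carry a co-timed EMG burst at 4×
baseline RMS with 100-ms ramps spanning the full event, making the
EMG-overlap ground truth unambiguous. For T+ events the generator inserts
the stage change so the onset falls inside the classifier's own
half-epoch windows; planted onsets keep ≥120 s spacing so that no event
sits within 15 s of another event's inserted boundary, and T− events stay
≥20 s from any change. Stage-profile amplitudes are calibrated so that no
detection band's power ratio across a stage border exceeds the local
multiplier of 2 — stage borders are not arousals and must not be scored
as such.

The per-stage spectra, boosts and EMG parameters are configurable;
defaults mirror the targeted recording setup (200 Hz, 11 EEG derivations
re-referenced recordings, submental EMG, 8-h nights, 30-s stages).

What the generator does **not** emulate: spindle/slow-wave coupling to
arousals, apnea or limb-movement events, heavy-tailed artifact
distributions, and volume-conduction topography beyond a global gain.
Consequently, passing the recovery tests shows the pipeline implements
its rules exactly and recovers events of the stated effect size under
realistic band-power contrast — it does not certify detector sensitivity
on real recordings, where background nonstationarity is richer.

`simulate_cohort()` has two modes: a fast statistical mode drawing
per-subject densities around configurable baselines (truncated normal,
T−M+ most prevalent at 5/h), and an end-to-end mode measuring densities
from full per-subject synthetic nights. Amyloid is generated as
intercept + age effect − 2.3 × T−M+ density + 4.5 × T+M− density + noise
(SD 12 Centiloid); these defaults put the two terms' semipartial R²
near 0.13 and 0.08 at n = 100, the effect-size scale reported for this
design, and the attention effect (0.2 raw-score units per event/h)
targets R²β ≈ 0.05. All generating parameters are stored with the table
for recovery tests.

## Numerical notes

* Time is seconds from recording start; intervals are half-open; epoch
  *k* (0-based) covers `[30k, 30k+30)`. This removes every off-by-one
  ambiguity between detection, typing and metrics.
* EDF amplitudes are taken from the file's physical-range fields; no
  further calibration is applied because the detector is
  scale-invariant. Round trips are exact to the 16-bit quantization step
  of the declared range.
* The Morlet family uses unit-energy kernels truncated at ±3.5σ; events
  near the recording edge that lack the 500-ms baseline or the 3-s window
  raise a `margin-error` and are skipped with a log message, never
  silently.
* Problem sizes used by the packaged checks — a single 8-h night at
  200 Hz for detection recovery, 200 replicate cohorts of n = 100 in fast
  statistical mode for calibration and recovery — were chosen as the
  smallest sizes at which the binomial uncertainty of a 5% rejection rate
  (±2 SE ≈ ±3 points) is informative.

## Known limitations

* The exact EMG criterion and several operational definitions (WASO tail
  handling, sleep-onset rule, awakening run length) of the reference
  analyses are unpublished; all are implemented as documented defaults
  with configuration switches.
* The gamma branch of the density model reports Wald chi-square tests
  rescaled to the F scale with residual denominator dfs — an
  approximation, noted in the result object whenever it is taken.
* Printed association statistics from the motivating cohort cannot be
  reproduced here because that cohort is not deposited; the models are
  validated structurally (calibration, sign recovery, CI coverage)
  against the bundled generator instead.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, duration_h = 8)
sim <- simulate_psg(cfg)
events <- detect_arousals(sim$recording, sim$hypnogram)
flags <- emg_tone_flags(emg_signal(sim$recording), 200)
typed <- classify_events(events, sim$hypnogram, flags)
evaluate_detection(typed, sim$truth)
sleep_metrics(typed, sim$hypnogram)

cohort <- simulate_cohort(cohort_config(seed = 2, n_subjects = 100))
fit_abeta_model(cohort)
```
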