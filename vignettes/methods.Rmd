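---
title: "Methods: staging, event detection and statistics in swdscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staging, event detection and statistics in swdscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`swdscore` quantifies rodent polysomnography for genetic-epilepsy studies:
it scores wake/NREM/REM vigilance states from two EEG channels and one EMG
channel, detects spike-wave discharges (SWD, 6–12 Hz), slow spike-wave
discharges (SSWD, 3–6 Hz) and sleep spindles (10–15 Hz), estimates NREM
delta power by multitaper spectral analysis, and summarises per-animal
incidence metrics with group statistics. A ground-truthed synthetic
generator provides records on which every stage can be validated without
recorded data. This vignette documents the model behind each stage, the
tunable parameters, the numerical choices, and what validation on
synthetic data does and does not establish.

## Signal model and preprocessing

A record holds two EEG channels and one EMG channel (mV) on a common time
grid, with time in seconds from record start and all intervals half-open
`[onset, offset)`. Acquisition-style band-pass filters (EEG 0.1–100 Hz,
EMG 0.1–400 Hz) are 4th-order Butterworth applied forward–backward
(zero-phase), realised as cascaded high-pass + low-pass sections because a
direct band-pass whose edges span three decades is numerically fragile at
kHz rates. Analysis proceeds at 200 Hz after anti-aliased decimation
(8th-order low-pass at 0.8 of the target Nyquist, then subsampling;
polyphase resampling for non-integer ratios).

Movement artifacts are flagged from EMG power: seconds whose 1-s EMG RMS
exceeds `center + k_sd * spread` for at least `min_dur_s` (defaults
`k_sd = 5`, `min_dur_s = 0.5` s), merged when closer than 1 s. Because EMG
RMS is strongly bimodal across the sleep/wake cycle (atonia vs waking
muscle tone), a median/MAD rule computed over the whole record collapses:
with sleep occupying more than half the record, the median and MAD sit
inside the atonia mode and *all* waking tone gets flagged. The center is
therefore the median of the upper mode (seconds at or above the overall
median RMS) and the spread is the quantile-based robust SD
`(q90 − q50)/z₀.₉`, which neither collapses on bimodal records nor
underestimates spread on unimodal ones. Movement artifacts in real
recordings are usually confirmed by video; this EMG-power proxy is the
reproducible stand-in, and epochs more than half covered by the mask are
excluded from every downstream denominator.

## Vigilance-state staging

Scoring uses the standard criteria — wake: low EEG amplitude with large
EMG amplitude; NREM: high EEG amplitude with dominant frequency below
4 Hz; REM: uniform low-amplitude EEG with dominant 6–10 Hz theta — on a
10-s epoch grid with 1-s sub-epochs. Those criteria are qualitative, so
the classifier fixes quantitative cuts, calibrated per record:

* `emg_wake_cut`: the midpoint (in log space) between the two modes of the
  log EMG RMS density (fallback: 60th percentile when no bimodality is
  found). EMG tone is the most reliable wake marker.
* `eeg_amp_cut`: the median broadband (0.5–30 Hz) envelope over the
  record. "High" NREM amplitude means above this median.
* `delta_frac_cut = 0.5` and `theta_ratio_cut = 1.5`: fixed defaults,
  overridable through `swd_config(staging = ...)`. Delta fraction is
  delta power (0.5–4 Hz) over total power (0.5–30 Hz); the theta ratio is
  theta (6–10 Hz) over delta power.

Per 1-s sub-epoch the decision rule is: wake if EMG RMS exceeds the wake
cut; else NREM if the delta fraction and the envelope exceed their cuts;
else REM if the theta ratio exceeds its cut at low envelope; otherwise the
nearest state by normalised distance to the cuts. In that fallback the EMG
distance is measured in octaves (log2) below the cut — EMG tone lives on a
log scale, and a linear distance saturates at 1, which let "wake" win on
SWD-dense NREM seconds whose spectral shape the discharge distorts.

The epoch label is the state occupying more than 5 of its 10 seconds. An
exact 5 s/5 s split keeps the previous epoch's state (hysteresis): the
dominance rule is only defined for a majority, and ties need a
deterministic resolution. The epoch grid is the staging unit: downstream
state conditioning (event baselines, incidence by state) uses the
epoch-smoothed per-second labels, while the raw sub-epoch labels that fed
the dominance rule are retained in the hypnogram (`state_raw`). Raw
sub-labels are unreliable exactly where it matters — during an epileptic
discharge the 1-s spectral features no longer look like the surrounding
state — and epoch smoothing is what a human scorer implicitly does.

Durations are epoch counts times 10 s; a bout is a maximal run of epochs
in one state (artifact epochs break runs); transitions are counted between
consecutive non-artifact epochs with different labels. Durations plus
artifact time conserve the hypnogram span exactly.

## Multitaper spectral estimation

Power spectral densities are DPSS (Slepian) multitaper estimates. Tapers
come from the classic symmetric tridiagonal eigenproblem, are unit-energy,
and are cached per window length since the pipeline reuses a handful of
sizes. Defaults `nw = 4`, 7 tapers for 10-s windows are common multitaper
practice for EEG; short 1-s staging windows use `nw = 2`, 3 tapers. The
one-sided density is normalised so that `sum(psd) * df` equals the biased
variance estimate (Parseval); white-noise calibration and exact quadratic
amplitude scaling are asserted in the tests.

The NREM delta-power statistic averages, over the first 30 min of
NREM-scored 10-s windows in record order, the band-average PSD in
0.1–4 Hz, averaged over the two EEG channels (which channel the original
procedure used is not stated; averaging is the symmetric choice). NREM is
fragmented, so "30 continuous minutes" is read as the first 1800 s of
NREM-labeled windows, not contiguous wall-clock time — the only executable
reading. Windows in REM/wake or overlapping artifacts are excluded. Two
delta bands coexist on purpose: staging uses 0.5–4 Hz, the delta-power
statistic uses 0.1–4 Hz as printed; both live in `swd_config()$bands`.
When a record holds less than 30 min of NREM the function refuses by
default; cohort drivers may pass the available amount explicitly.

## Event detection

"Amplitude" is operationalised as the analytic-signal envelope. For
detection the envelope of a band is computed by FFT band-selection: the
spectrum is masked flat over the band with raised-cosine transitions
(0.5 Hz) outside it, restricted to positive frequencies, and inverted.
Unlike an IIR band-pass, the in-band response is exactly flat — a
Butterworth band-pass loses half its squared magnitude at the band edge
after forward–backward filtering, which silently attenuates events whose
frequency falls near 6 or 12 Hz and degrades recall at threshold
amplitudes.

SWD/SSWD detection per EEG channel:

1. **Baseline.** For wake/REM the baseline is the median broadband
   (0.5–30 Hz) envelope over the preceding 10 s of same-state,
   artifact-free, event-free signal (expanding to 60 s when too few
   seconds are eligible; no eligible baseline rejects the candidate).
   During NREM, delta amplitude is itself large, so the baseline is the
   median *delta-band* (0.5–4 Hz) envelope instead. Baselines are
   two-stage medians (median over per-second median envelopes), which
   makes them robust to brief transients. "Event-free" is resolved by a
   two-pass scheme: pass 1 estimates baselines excluding only artifacts,
   pass 2 re-estimates them excluding pass-1 detections and re-detects.
2. **Threshold.** Envelope at or above `mult ×` baseline, with
   `mult = 2.0` in wake/REM and `mult = 1.5` in NREM. The multiplier is
   applied per 1-s state label; for events contained in one state this is
   identical to choosing the multiplier by the state at onset, and it is
   the only non-self-referential reading when a candidate straddles a
   state boundary.
3. **Candidates.** Sub-threshold gaps shorter than 0.3 s are closed (one
   missed spike–wave cycle at 6–12 Hz is 83–167 ms), runs of at least 1 s
   are kept, and candidates overlapping the artifact mask are discarded.
4. **Refinement.** The onset moves backward to the last sample before the
   candidate whose absolute broadband value is at or below the baseline
   (the leading edge crossing the precedent baseline) and the offset
   forward symmetrically, each bounded to 1 s.
5. **Rhythmicity.** At least 60% of the event's broadband power must lie
   in the detection band, measured on a Hann-tapered periodogram of the
   event span (again no in-band roll-off), and the peak frequency must
   fall in the band. This implements "trains of rhythmic biphasic spikes"
   without template matching and rejects broadband transients.
6. **Kind conflicts.** Overlapping SWD (6–12 Hz) and SSWD (3–6 Hz)
   detections on a channel resolve to the kind with the higher envelope
   ratio over its baseline.
7. **Laterality.** Same-kind events on the two channels whose overlap is
   at least half the shorter event merge into one bilateral event spanning
   the union; unmatched events are left/right (focal). Each event takes
   the vigilance state at its onset, which matches incidence counting by
   state even for boundary-straddling events.

Sleep spindles (10–15 Hz) are detected with the envelope threshold
`baseline mean + 1.5 × baseline SD` over the preceding 10 s of same-state
signal, keeping events of 0.5–5 s; events overlapping a detected SWD/SSWD
are discarded (the 10–12 Hz bands overlap and epileptic events take
precedence). Two operational constraints make the 1.5-SD criterion usable
on continuous signals, where the envelope of stochastic band-limited
background grazes such a threshold frequently: detection runs on a
0.25-s-smoothed envelope while the baseline SD is taken from the raw
envelope (so the threshold sits several smoothed-SDs above the mean), and
spindle calls must be bilaterally concordant and within NREM — spindles
are bilaterally synchronous thalamocortical NREM events, whereas chance
background runs are unilateral. Both constraints are config-overridable
(`spindle_bilateral_only`, `spindle_states`). Even so, spindle counts on
stochastic backgrounds retain a small false-positive floor; on default
synthetic records the measured density runs of order 10–20% above the
injected rate.

Detection is fully deterministic: identical record and configuration give
byte-identical event tables.

## Incidence metrics and statistics

Per state: event count, total event duration, count per hour of that
state, duration per hour of that state, and percent of state time —
all exact arithmetic on counts and durations. Spindle density is spindle
count over NREM seconds (Hz). Group comparisons report mean ± SEM with
classical pooled-variance Student t-tests (paired or unpaired; Welch by
flag), one-way fixed-effects ANOVA, and a hand-implemented Holm–Šidák
step-down adjustment (`1 − (1 − p₍ᵢ₎)^(m−i+1)` with running-maximum
monotonicity) for pairwise follow-ups, since `stats::p.adjust` offers
Holm–Bonferroni but not the Šidák variant. A paired comparison of
identical vectors reports t = 0, p = 1 with a `degenerate` flag rather
than failing; a constant nonzero paired shift reports a signed infinite t
with p = 0 and the same flag. Significance is fixed at 0.05.

## The synthetic generator

The generator emulates the study conditions so that every pipeline stage
is testable against ground truth:

* **State architecture.** Semi-Markov alternation (wake→NREM;
  NREM→REM 0.35 / wake 0.65; REM→wake 0.8 / NREM 0.2) with log-normal
  dwell times (means 120/180/60 s for wake/NREM/REM, σ_log = 0.6,
  truncated at 10 s) — fragmented murine sleep with bout durations of the
  order reported for epileptic knock-in animals.
* **Signals.** EEG per channel is a 1/f^0.7 background (state-dependent
  RMS) plus state-gated band-limited components — 0.8–3.5 Hz delta in
  NREM, 6–9.5 Hz theta in REM — with 0.5-s raised-cosine crossfades at
  transitions; the two EEG channels share half their variance. EMG is
  broadband noise with state-gated RMS (0.06 mV wake, 0.008 NREM,
  0.004 REM). Amplitudes (bg 0.05 / delta 0.18 / theta 0.055 mV RMS) were
  chosen once so the staging criteria hold with realistic margins: NREM
  delta fraction ≈ 0.9, wake ≈ 0.35, REM theta/delta ≈ 7. The background
  exponent 0.7 keeps the wake delta fraction below 0.5 (a steeper 1/f
  background would put more than half of broadband power into the delta
  band even in wake). Band-limited components are synthesised at a 100-Hz
  internal rate and interpolated to the native rate (default 1 kHz, so
  the 200-Hz resampling path is exercised); all staging/detection bands
  lie far below the internal Nyquist.
* **Events.** Poisson placement per state (default SWD rates 120/20/30
  per hour of NREM/REM/wake; SSWD 15/0/5; spindles 54 per NREM hour
  ≈ 0.015 Hz, in the range of reported murine spindle densities), thinned
  so events never overlap and only start where 10 s of same-state history
  exists within 60 s (so a pre-event baseline is defined). SWD waveforms
  are stylised spike–wave cycles — a fundamental drawn in the kind's band
  plus a 0.4-amplitude second harmonic with phase offset — scaled to
  `amp_mult` (default 3) times the expected state-conditioned baseline
  envelope and placed bilaterally with probability 0.9. Spindles are
  Tukey-windowed (quarter-duration cosine ramps) sinusoids of 0.6–2.5 s: a
  strict Hann envelope spends so little time near its peak that a
  1.5-s spindle would cross the amplitude threshold for well under the
  0.5-s minimum duration, contradicting the waxing–waning events the
  detector is specified to keep.
* **Cohorts.** Per-animal log-normal random effects multiply event rates
  (σ_log = 0.3) and EEG amplitudes (σ_log = 0.15) — a modelling choice;
  only group means ± SEM are reported for the source data. Group F
  animals have their NREM delta amplitude multiplied by `sex_effect`
  (default 2); the `post` phase of a pre/post design multiplies the NREM
  dwell mean (1.5) and SWD/SSWD rates (1.7), a phenomenological stand-in
  for slow-wave-oscillation induction; no neural dynamics are simulated.
  The SWO induction timing itself (0.5 Hz for 10 min: 1800 ms down,
  200 ms up with a 20-ms pulse at each up-state start) is generated by
  `swo_protocol_track()` for protocol bookkeeping.

What passing on synthetic data shows — and what it does not: the generator
realises exactly the spectral/EMG contrasts the classifier thresholds on,
so staging accuracy ≥ 95% on it demonstrates internal consistency of
criteria and classifier plus robustness to epoch-grid misalignment and
event contamination, not human-level scoring of real mouse EEG. Real
records add breathing and electrode artifacts, non-stationary baselines,
and state transitions that are not 0.5-s crossfades. The detector results
likewise certify the operating point at the stated amplitude multipliers
on stylised morphologies, not performance on every natural SWD waveform.

## Problem sizes and numerical choices

Validation runs use a 6-h record at 1 kHz native rate for staging
recovery, a 2-h record for the detector operating point at 2.5× amplitude,
cohorts of 6–13 animals per cell at 200 Hz native rate (60–75 min per
record) for design recovery, and 20 random 60-s records for the
brute-force detector oracle — sizes at which the Poisson and sampling
error of every asserted quantity sits well inside its tolerance.
Tolerances: Parseval within 10% (finite-window bias of the taper family);
flat-band delta-power recovery within 15% (taper leakage at the 0.1-Hz
band edge); amplitude-scaling exactness at 1e-9 relative; t/F oracle
agreement at 1e-10. Degenerate inputs are defined, not fatal: zero signals
give zero features and empty event lists; constant features refuse
calibration; zero-variance comparisons carry a flag.

## Known limitations

* The staging cuts are fixed, not learned; records whose EMG is not
  bimodal (e.g. continuous recording failure) fall back to a percentile
  cut and should be reviewed.
* The video-free artifact proxy cannot see movement without EMG
  elevation, and its threshold statistics assume artifacts are rare.
* The NREM ×1.5 rule is applied to both SWD and SSWD; the source
  procedure is explicit only for SWD.
* Spindle detection inherits the false-positive floor discussed above;
  absolute spindle densities should be compared within, not across,
  detector configurations.
* GTCS/behavioural seizure classification, multi-unit activity and
  optogenetic physiology are out of scope.
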