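# swdscore

Quantification of rodent EEG/EMG polysomnography for genetic-epilepsy
studies: vigilance-state staging, spike–wave-discharge and sleep-spindle
detection, NREM delta-power estimation, and per-animal incidence
statistics — with a ground-truthed synthetic polysomnography generator so
the whole chain is testable without recorded data.

In mouse models of genetic epilepsy (e.g. GABA-A receptor subunit
knock-ins modelling Dravet syndrome), epileptic spike–wave discharges
(SWDs) occur preferentially during NREM sleep, and quantifying that state
dependence requires a reproducible chain from raw signals to group
statistics. `swdscore` implements that chain:

* **Staging.** 10-s epochs scored wake/NREM/REM from two EEG channels and
  one EMG channel: wake = low EEG amplitude + high EMG tone, NREM = high
  EEG amplitude with delta (0.5–4 Hz) dominance, REM = low amplitude with
  theta (6–10 Hz) dominance. Each epoch takes the state occupying > 5 s of
  its 1-s sub-epochs.
* **Event detection.** SWDs (6–12 Hz) and slow SWDs (3–6 Hz) as envelope
  trains > 1 s at ≥ 2× the preceding baseline amplitude in wake/REM and
  ≥ 1.5× the preceding delta amplitude in NREM (delta is itself large
  there); onset/offset refined to the baseline crossing; bilateral events
  merged across channels. Sleep spindles (10–15 Hz) at
  baseline mean + 1.5 SD with 0.5–5 s duration gates.
* **Spectra.** DPSS multitaper PSD (`nw = 4`, 7 tapers, 10-s windows);
  NREM delta power = band-average PSD over 0.1–4 Hz across the first
  30 min of NREM windows, in mV²/Hz.
* **Statistics.** Per-state incidence (#/hr, s/hr, % of state time),
  spindle density (Hz), mean ± SEM, Student paired/unpaired t-tests,
  one-way ANOVA with Holm–Šidák follow-up.
* **Synthesis.** `generator_spec()` / `simulate_record()` /
  `make_cohort()` produce records with exact ground truth (state track,
  injected events, artifacts) including sex effects on NREM delta
  amplitude and pre/post phase effects on SWD rates.

I/O covers EDF and delimited text for signals, plus CSV event tables,
hypnograms, and cohort reports.

## Worked example

Simulate one hour of ground-truthed polysomnography, run the pipeline,
and compare with the truth:

```r
library(swdscore)

spec <- generator_spec(duration_s = 3600, rate = 1000, seed = 42)
sim  <- simulate_record(spec)

res <- run_pipeline(sim$record)   # preprocess -> stage -> detect -> summarise
res$incidence
#> # A tibble: 3 × 7
#>   state duration_h event_count event_total_dur_s events_per_hr event_dur_s_per_hr event_pct_of_state
#>   <chr>      <dbl>       <int>             <dbl>         <dbl>              <dbl>              <dbl>
#> 1 wake      0.422           16             48.4           37.9              115.                3.19
#> 2 NREM      0.506           51            198.           101.               391.               10.9
#> 3 REM       0.0722           2              6.58          27.7               91.2               2.53

staging_accuracy(res$hypnogram, truth_hypnogram(sim$truth))
#> [1] 0.9972222
match_events(res$events, sim$truth$events)[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 0.9857143
```

The incidence table reads: this synthetic "animal" spent 0.51 h in NREM
and showed 101 SWDs per NREM hour occupying 11% of NREM time — the
NREM-preferential pattern the generator encodes (120/20/30 events per
hour of NREM/REM/wake) — while staging matched the ground-truth hypnogram
on 99.7% of epochs and the detector recovered the injected discharges
with precision 1.0 and recall 0.99. `autoplot()` methods draw
hypnograms, PSDs, spectrograms and cohort summaries; `tidy()`/`glance()`
summarise fitted comparisons.

Group-level analysis follows the same grammar:

```r
design <- tibble::tibble(genotype = "het", sex = c("M", "F"), n = c(6, 6))
coh <- make_cohort(design, generator_spec(duration_s = 3600, rate = 200),
                   seed = 1, phases = c("pre", "post"))
# ... per-animal run_pipeline() + animal_metrics_row(), then:
# cohort_report(animals, comparisons)  ->  means ± SEM, t/F, Holm–Šidák
```

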