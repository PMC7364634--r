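# tausleep

Longitudinal rodent sleep-EEG analysis for tauopathy phenotyping.

Progressive tauopathy models (the bitransgenic rTg4510 mouse and its
controls: wild-type, tTA transactivator-only, and doxycycline-suppressed
transgenics) develop a characteristic polysomnographic signature as pathology
advances: EEG spectral power declines, dark-phase wakefulness rises, and REM
sleep fragments into episodes too short to qualify as bouts. `tausleep`
implements the full analysis chain needed to quantify that signature from
chronic EEG/EMG recordings — and, because no recordings of this kind are
publicly deposited, ships a first-class synthetic-data generator that
reproduces the statistical structure every downstream stage assumes, so the
whole chain is testable end to end.

The package is aimed at sleep physiologists and biostatisticians working
with chronic rodent EEG: it is organised as a set of composable analysis
stages (an R function per operation) plus numbered driver scripts under
`analysis/` that walk through a complete simulated study.

## What it computes

- **Synthetic cohorts** (`simulate_hypnogram`, `synthesize_signals`,
  `simulate_study`, `synthesize_video`): circadian two-phase Markov chains
  over the four scored arousal states (wake, theta-dominated wake, NREM,
  REM); state-conditional EEG (band-limited oscillators meeting per-state
  band-power targets in uV^2) and EMG (white noise at the state's RMS tone);
  clipping/flat-line artefact injection; a progressive transgenic
  trajectory (geometric power decline, dark-phase wake redistribution, REM
  fragmentation, motion increase); terminal atrophy values coupled to
  realised severity; greyscale home-cage video frames.
- **Per-epoch features** (`extract_features`): zero-phase Butterworth
  conditioning; 10-s epochs annotated by photoperiod; EMG RMS; Welch band
  power over delta (0.1-4], theta (5.1-9], alpha (9.1-12], beta (12-20] and
  total (0.1-30] Hz; period-amplitude (half-wave) incidence and mean peak
  amplitude per band, with each half-wave between consecutive baseline
  crossings assigned equivalent frequency f = 1/(2 x duration).
- **Staging** (`fit_templates`, `rank_membership_classify`,
  `score_recording`): individually optimised state templates (seeded or
  unsupervised k-means with semantic assignment), ranked-membership
  classification — for each feature the states are ranked by closeness of
  the epoch's value to each template, and the smallest mean rank wins —
  with EMG overrides separating REM atonia from theta-dominated wake.
- **Sleep metrics** (`detect_bouts`, `time_in_state`,
  `rem_episode_distribution`, `circadian_amplitude`, `weekly_aggregate`):
  sleep bouts (>= 3 consecutive NREM epochs or >= 2 consecutive REM epochs
  within a sleep run of >= 3 epochs), REM bouts (>= 2 epochs), state
  percentages per photoperiod, the REM episode-length histogram including
  sub-bout single-epoch episodes, and the light-minus-dark NREM amplitude.
- **Quality control** (`qc_epoch_flags`, `apply_week_exclusion`,
  `low_amplitude_flag`): clipping and flat-line detection per epoch and the
  strict "> 5% of epochs" week-exclusion rule.
- **Video locomotor activity** (`frame_motion`, `motion_trace`): changed
  pixels between consecutive 720 x 480 greyscale frames with an inclusive
  10-grey-level per-pixel threshold, summed per photoperiod.
- **Longitudinal statistics** (`fit_repeated_measures`,
  `pairwise_contrasts`, `back_transform`, `one_way_anova`,
  `correlate_with_atrophy`): least-squares means per group x age under an
  unstructured within-animal covariance; all 6 group pairs at each of 7
  ages (42 contrasts) with Tukey-Kramer adjustment; log-scale analysis with
  multiplicative back-transform for power and bout outcomes; terminal
  one-way ANOVA with Tukey HSD; Spearman correlation of terminal atrophy
  against final dark-period outcomes, on actual values and on group-mean
  centred residuals.

## Worked example

Score one simulated 12-h recording end to end:

```r
library(tausleep)

hy  <- simulate_hypnogram(photoperiod_schedule(),
                          default_transition_matrices(),
                          duration_hours = 12, seed = 101)
rec <- synthesize_signals(hy, fs = 100, seed = 102)
f   <- extract_features(rec)
tpl <- fit_templates(f, seed = 103)          # unsupervised templates
sc  <- score_recording(rec, tpl, features = f)
mean(sc$labels == hy$labels)                 # epoch-wise agreement
```

Running `analysis/02_score_recording.R` (which is exactly this) prints:

```
Scored 4320 epochs; epoch-wise agreement with truth: 99.9%
  WAKE        sensitivity 100.0% (n = 1226)
  THETA_WAKE  sensitivity 98.5% (n = 199)
  NREM        sensitivity 99.9% (n = 2287)
  REM         sensitivity 100.0% (n = 608)
```

i.e. per-animal templates plus ranked membership recover the generator's
truth hypnogram almost perfectly when the state spectra are well separated.
`analysis/03_sleep_metrics.R` then reports, for a simulated week, a
circadian NREM amplitude of 30.2 percentage points (light 54.8% NREM vs
dark 24.6%) and shows REM fragmentation at work: shrinking the REM
continuation probability to its week-44 transgenic level raises the share
of single-epoch REM episodes from 27% to 72% and more than halves the
number of qualifying REM bouts (1208 to 507) — continuity collapses while
total REM time falls far less. `analysis/04_group_statistics.R` fits the
full cohort: the transgenic delta-power decline becomes significant against
wild-type from week 32 (dark period), the wake increase later (week 40),
and terminal thickness separates the groups at F(3, 44) = 75.6.

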