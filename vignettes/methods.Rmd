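---
title: "Models and methods: simulating and analysing longitudinal rodent sleep EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and analysing longitudinal rodent sleep EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tausleep)
```

This vignette is the package's own account of the models it implements, the
choices made where the design was genuinely open, and what the synthetic
cohort does and does not establish about real recordings.

## The study design being modelled

A chronic polysomnography study in a regulatable tauopathy mouse: four
treatment groups — wild-type (WT), transactivator-only control (tTA), the
bitransgenic tau line (Tg) and the same line with the transgene suppressed
by doxycycline (TgDOX) — each recorded for one week every 4 weeks across
seven cycles (weeks 20 to 44), under a 12:12 light/dark schedule. The
recorded channels are one differential EEG (acquired at 400 Hz, bandpass
1–300 Hz) and one nuchal EMG (bandpass 10–100 Hz, reduced to RMS per 10-s
epoch). Each epoch is scored on-line into one of four arousal states: wake,
theta-dominated wake, NREM and REM. Because no dataset of this kind is
publicly deposited, the package treats the *generator* as part of the
deliverable: every analysis stage is validated against cohorts whose truth
is known by construction.

## The synthetic generator

**State dynamics.** Hypnograms are first-order Markov chains over the four
states at epoch resolution, with two transition matrices — one per
photoperiod phase — rather than continuous circadian modulation; two
matrices suffice to produce the light/dark contrasts the metrics quantify.
The defaults give stationary state fractions of roughly 55% NREM / 14% REM
in the light phase and 69% wake in the dark phase, the standard murine
pattern. Progressive phenotypes perturb the matrices analytically:
`increase_wake_fraction()` mixes the dark matrix with a wake-absorbing
kernel and solves (by root finding on the stationary distribution) for the
mixing weight that raises stationary wake by a requested number of
percentage points; `fragment_rem()` multiplies the REM self-transition
probability and redistributes the freed mass proportionally over the other
exits, so REM runs shorten without changing where exits go.

**Signals.** Each epoch's EEG is a sum of band-limited oscillators: three
random-phase sinusoids per band, with total variance equal to that state's
band-power target (µV²) and ±5% epoch-to-epoch power jitter. NREM is
delta-dominated (200 µV² target), REM and theta-dominated wake share a
5–9 Hz theta rhythm (100 µV²) and are separated *only* by EMG tone (0.3 vs
6 RMS units — REM atonia), and quiet wake is low-amplitude broadband. The
EMG is white noise normalised exactly to the state's RMS tone. A global
`amplitude_scale` multiplies the EEG waveform, so power scales with its
square — the knob that models progressive amplitude loss. By default the
generator is noiseless beyond the oscillators (all-zero targets give an
exactly zero signal, which pins down several degenerate-input contracts);
an optional `noise_floor_uv` adds amplitude-independent instrument noise,
and only in that regime does staging accuracy degrade as `amplitude_scale`
falls — the package's stand-in for the late-study recordings whose scoring
became unreliable.

The composition of theta-dominated wake is not specified anywhere
authoritative; the generator's choice — theta EEG at wake-level EMG — is an
assumption, made because it gives the stager exactly one discriminating
axis (muscle tone) between REM and theta wake, as in conventional rodent
scoring.

**The trajectory model.** `trajectory_spec()` encodes the progressive Tg
phenotype per 4-week cycle: a multiplicative band-power decline (default
10%/cycle from week 20, so week 44 sits at $0.9^6 \approx 53\%$ of
baseline), REM fragmentation (continuation probability ×0.85/cycle from
week 20), a dark-phase wake increase (+2.5 pp/cycle), and a dark-phase
motion increase (+8%/cycle). The wake redistribution is given its own onset
(week 28, two cycles after the spectral onset) because in the modelled
disease course the sleep-wake changes *follow* the initial spectral-power
changes; encoding that lag in the defaults is what lets the analysis chain
demonstrate the ordering rather than assume it. Per-animal heterogeneity
enters as a lognormal power intercept (sd 0.15 on the log scale), a normal
state-percentage intercept (sd 2 pp), and a lognormal frailty on the
decline rate (sd 0.15), with week-to-week noise of sd 0.10 (log power) and
2.5 pp (percentages) — magnitudes chosen once as typical of chronic rodent
EEG cohort variability.

REM continuity metrics follow the geometric run-length law implied by the
chain: with continuation probability $p$, run lengths are geometric, the
fraction of single-epoch episodes is $1-p$, qualifying bouts (length ≥ 2)
occur at rate $\text{runs} \times p$, and their mean length is
$(2 + p/(1-p))$ epochs. The metric-level study generator keeps the REM
*run-entry flow* constant while $p$ shrinks, which is what the transition
matrices do; fragmentation therefore yields fewer and shorter bouts and a
falling REM share simultaneously.

**Atrophy.** Terminal summed bilateral hippocampus + cortex thickness is
drawn per animal as group mean + coupling × (within-group standardised
realised severity) + residual noise, with severity proxied by the animal's
final dark-period NREM%. Group means (WT 6.0, tTA 5.9, Tg 4.4, TgDOX
5.7 mm) encode marked Tg atrophy and near-complete protection under
suppression; coupling 0.6 makes both the pooled ("actual") and the
within-group ("residual") correlation structures dialable.

**Scale.** `simulate_study()` generates outcomes at the metric level and
hypnograms on demand (`hypnogram_hours`), with raw signal synthesis opt-in
(`signal_hours`): a full cohort of week-long 400 Hz signals has no analytic
use here, while metric-level truth plus targeted signal-level fixtures
exercises every stage. Signal-level analyses in the tests and scripts use
24 h days at a 100 Hz working rate; all spectral code is rate-agnostic, and
at reduced rates the nominal acquisition band is capped at 95% of Nyquist
with a warning.

## Feature extraction

Conditioning is a 4th-order Butterworth applied forwards and backwards
(zero phase), so half-wave timing is undistorted; the working band is
0.5–30 Hz. Band powers integrate a Welch PSD (2-s Hann segments, 50%
overlap, segment means removed) over half-open intervals (lo, hi]: delta
(0.1, 4], theta (5.1, 9], alpha (9.1, 12], beta (12, 20], total (0.1, 30].
Half-open edges put the 4–5.1 and 9–9.1 Hz gaps outside every named band,
exactly as the band table prints them; a consequence asserted throughout is
that the four named powers can never sum above total power. The 2-s segment
gives 0.5 Hz resolution — enough to separate the bands while averaging five
segments per 10-s epoch.

Period-amplitude analysis cuts the mean-centred epoch at baseline
crossings (strict sign changes between adjacent samples); each half-wave
carries equivalent frequency $f = 1/(2\,\text{duration})$ and its peak
absolute amplitude, accumulated per band as incidence and mean amplitude.
Two conventions required a decision, since half-wave extraction is named
but nowhere operationalised: (1) edge segments not delimited by two
crossings are discarded — a 10-s 2 Hz sine therefore yields 38–40 delta
half-waves rather than exactly 40; (2) half-waves shorter than
$1/(2 \times 30\,\text{Hz})$ are dropped, suppressing sample-noise
crossings above the 30 Hz analysis ceiling. No hysteresis is applied. The
implementation is held exactly equal (counts identical, amplitudes to
1e-9) to a brute-force sample-scanning oracle in the tests.

## Staging

Templates are per-animal and per-week ("individually optimised"), refit
each cycle so they track amplitude drift. Unsupervised fitting runs k-means
(k = 4, 20 restarts, deterministic seeding, up to 20 attempts on degenerate
partitions) on standardised features, then assigns semantics: highest delta
power → NREM; of the rest, lowest EMG → REM; of the remaining two, lower
theta/delta ratio → wake, the other theta-dominated wake. EMG thresholds
sit at midpoints between state EMG medians (REM–NREM midpoint for atonia,
NREM–wake midpoint for wake).

Classification is ranked membership realised as mean-of-ranks: for each
feature, states are ranked by closeness of the epoch's standardised value
to each template (ties share the minimum rank); the smallest mean rank
wins, with ties broken by standardised Euclidean distance and then a fixed
state order (NREM, REM, THETA_WAKE, WAKE). Two EMG overrides follow: REM
calls above the atonia threshold become theta wake, and wake/theta-wake
calls with atonia *and* theta dominance become REM. No temporal smoothing
is applied by default — scoring is per-epoch, as on-line scoring is — with
an optional 3-epoch majority filter behind a flag. The classifier is
scale-invariant by construction (standardisation absorbs any global EEG
gain when templates are refit), a property the tests assert directly. The
exact feature set and ranking statistic of the original proprietary scorer
are unpublished; this module is a reproducible stand-in defined by its
contracts, not a replica.

## Sleep metrics

A sleep bout is a maximal run of sleep epochs (NREM + REM) that contains
≥ 3 consecutive NREM epochs or ≥ 2 consecutive REM epochs *and* spans at
least 3 epochs. The two printed rules conflict at exactly one point — an
isolated 2-epoch REM run is a bout by the consecutive-epoch rule but
violates the "> 30 s" convention for sleep bouts — and the package resolves
it in favour of the 30-s minimum, with `min_sleep_epochs = 2` available for
the literal reading (the run-content rule itself can also be restricted to
NREM via `sleep_rule = "nrem_only"`). REM bouts are maximal REM runs of
≥ 2 epochs (≥ 20 s) under every reading. Artefact epochs terminate runs —
the conservative continuity choice. State percentages use scorable
(non-artefact) epochs as the denominator so that exclusions do not deflate
state time, and theta-dominated wake is merged into wake for all
architecture metrics while the 4-state labels are preserved in the
hypnogram. Weekly aggregation is an unweighted mean over retained days.

## Quality control

Thresholds are not specified by any authority, so the defaults were chosen
to separate generator artefacts perfectly and are config-exposed: clipping
flags an epoch when ≥ 1% of samples sit within 98% of the week's amplitude
rail in runs of ≥ 5 samples; flat-line flags any 2-s window with variance
below 1e-3 µV²; the week-exclusion rule is strict — a week is dropped only
when artefacts *exceed* 5% of epochs, so exactly 5% is retained. Exclusion
granularity is the animal-week, with no partial-day salvage. A
low-amplitude flag (median weekly total power below 20% of the animal's
first-week median) marks weeks where staging-dependent outcomes should be
dropped while raw power is retained. The original study's artefact review
was expert and manual; these automated rules are a stand-in.

## Longitudinal statistics

The repeated-measures model is estimated by the cell-means (profile)
approach: least-squares means are the group × age cell means, and the
within-animal covariance across ages is unstructured, pooled over groups
from residual cross-products with pairwise-complete handling of missing
weeks (the design loses animal-weeks to QC). This is deterministic — no
iterative likelihood — and under balance reproduces a GLS fit with
unstructured correlation and per-age variances exactly, which the tests
verify against `nlme::gls` + `emmeans`.

Contrasts cover all 6 group pairs at each of 7 ages (42 comparisons).
Standard errors use the age-specific variance with Kramer's unequal-n
correction; adjusted p values come from the studentized-range distribution
with k = 4 means. Whether the published adjustment treated the 42 contrasts
as one family or as 7 per-age families is not stated; the default here is
per-age families (matching per-timepoint significance marking), with a
`family = "global"` mode that adds a Bonferroni factor across ages. The
arbiter is the global-null simulation: at n = 12/group under an
unstructured covariance, the per-family type-I error over 500 replicates
is ≈ 0.05 (the acceptance band is [0.03, 0.07]).

Power and bout outcomes are analysed on the natural-log scale and
back-transformed, so contrasts read as multiplicative ratios (a ratio of
0.53 at week 44 *is* the six-cycle 10% decline). Terminal measures use
classical one-way ANOVA with Tukey HSD. Atrophy correlations are Spearman,
in two modes: "actual" pools raw pairs across groups (sensitive to
group-mean separation), while "residual" centres both variables by group
mean first (sensitive only to within-group association). "Spearman
residuals" has no published definition; group-mean centring is this
package's interpretation, chosen because it cleanly reproduces the
dissociation of interest — group-shift-only constructions give pooled
|rs| > 0.5 with residual |rs| near zero. p values use the t-approximation,
or the exact null distribution below n = 12 when there are no ties.

## Video locomotor activity

Frame differencing counts pixels whose grey level changes by at least 10
(inclusive) between consecutive 720 × 480 frames. The printed threshold
sentence is ambiguous between a per-pixel grey-level change of ≥ 10 and a
frame-level floor of ≥ 10 changed pixels; the per-pixel reading is the
default because compression noise acts per pixel, and a frame-level floor
is available as an option. The count is exactly equal to a per-pixel loop
oracle in the tests, invariant to sub-threshold global luminance shifts,
and deliberately saturates to the full frame on a supra-threshold lighting
step — a documented sensitivity, not a bug. Per-period "relative distance"
is the sum of counts over each photoperiod's frames, in arbitrary units;
the camera frame rate only sets resolution (config default 25 Hz).

## Problem sizes, determinism, degenerate inputs

Every generator is a pure function of its spec and an integer seed (RNG
state is saved and restored around each draw). Signal-level validations use
24-h, 100 Hz days (8,640 epochs); chain-convergence checks use ~10,000
epochs; the null-calibration simulation uses 500 replicates of the full
4 × 7, n = 12 design; effect-recovery runs use n = 15/group at metric
level. These sizes were chosen so that each check's Monte-Carlo error is
small against the tolerance it is held to. Degenerate inputs are contracts,
not accidents: empty recordings warn and return empty epoch lists;
identical epochs make template fitting fail loudly; all-artefact periods
are flagged undefined and excluded; zero-variance correlation inputs are
flagged degenerate rather than returning NaN.

## What passing tests do and do not show

The synthetic cohort has well-separated state spectra, stationary
within-phase dynamics, exactly epoch-aligned artefacts and noiseless
oscillator EEG. Staging agreement near 99% on such data demonstrates the
*correctness of the chain* — features, templates, ranking, overrides,
metrics, statistics — not the field accuracy of any scorer on real mice,
where spectra overlap, transitions are gradual, and artefacts straddle
epochs. Likewise the effect-recovery runs show the statistical pipeline
detects the programmed phenotype at realistic n and noise; they are not a
power analysis for any real study. The correlation, FWER and bout-rule
results, by contrast, are properties of the algorithms themselves and
transfer directly.
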