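---
title: "Quantifying behavioral responses to an acute disturbance from bio-logger data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying behavioral responses to an acute disturbance from bio-logger data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoglog)
```

## The problem

hoglog analyzes multi-logger field deployments in which a small set of
free-ranging, nocturnal animals (the motivating system is urban European
hedgehogs carrying GPS/accelerometer back-packs and VHF tags) is observed
over a baseline phase and an acute anthropogenic disturbance phase of equal
length — in the motivating deployment 19 + 19 days around a large music
festival in a city park. The question is not whether the *average* animal
changed its behavior but how *each individual* changed, across several
complementary behavioral axes:

* **space use** — nightly 50% kernel-density core areas from GPS;
* **behavior budgets** — per-day counts of immobility, balling up,
  locomotion and unclassified ("other") behavior, predicted per minute from
  triaxial acceleration bursts by a gated SVM;
* **circadian timing** — the diurnality index (DI), the onset of nightly
  activity relative to civil dusk (TSdusk), and daily sums of overall
  dynamic body acceleration (ODBA);
* **circadian integrity** — the Degree of Functional Coupling (DFC), the
  share of the activity spectrum locked to harmonics of the 24-h day;
* **nest fidelity** — Kaplan–Meier survival of nest-utilization spells and
  a log-rank comparison between phases, per sex.

Because the motivating study's raw logger streams are not publicly
deposited, the package ships a synthetic study generator with complete
ground truth; every pipeline stage is exercised and validated against that
generator or against closed-form oracles.

## Data model

Accelerometers record one *burst* per minute: 2.5 s (optionally 2.64 s) of
100-Hz triaxial samples, i.e. 1440 bursts for a complete day. GPS wakes
every 5 min between 19:00 and 07:00 and takes a burst of five fixes.
Nest checks are daily. Civil dawn/dusk instants arrive as an external
twilight table. All timestamps use a fixed-offset study-local timezone
(UTC+2), so no DST logic exists anywhere in the pipeline.

Days are anchored two ways, deliberately: behavior budgets and daily ODBA
sums use the civil calendar day (00:00–23:59) with a completeness filter —
a day enters only with at least 1430 of 1440 bursts, so partial days cannot
bias budgets toward behaviors of a particular time of day — while DI,
activity onset and TSdusk use a dawn-to-dawn "activity day", which keeps a
full night of activity inside one analysis day.

## Burst features and behavior classification

Each validated burst (under-length bursts are dropped; over-length bursts
truncated with a warning) yields 25 predictors: per axis the mean, standard
deviation (n−1), inverse coefficient of variation (mean/sd; flagged missing
at zero variance rather than returned as ±∞), variance, raw kurtosis,
skewness and the weighted mean frequency of the autocorrelated power
spectrum; plus the static-vector norm *q*, pitch, roll (x-forward, z-up,
degrees) and ODBA. The static component of a burst is its whole-burst mean
— the burst is far too short for the running-mean windows used on long
continuous records — and ODBA is the mean summed absolute dynamic
acceleration, hence exactly invariant to gravity offsets. The accumulated
standard deviation aSD = sd_x + sd_y + sd_z is carried alongside as the
activity proxy for all rhythm metrics; it is not a model predictor.

Kurtosis is the raw (non-excess) standardized fourth moment; the convention
is stated here because only a constant offset separates the alternatives.
The spectral weighted mean uses the *circular* autocorrelation, whose
discrete Fourier transform is exactly the signal's periodogram
(Wiener–Khinchin). The one-sided linear autocovariance was rejected after a
numerical check: its implicit triangular taper spreads a pure spectral line
into slowly decaying sidelobes, dragging the weighted mean of a clean 2-Hz
tone to ~9.7 Hz, while the circular form returns 2.0 exactly.

Classification is a one-vs-one multiclass SVM (RBF kernel, default
`cost = 1`, `gamma = 1/25`, pairwise-coupled probability calibration, fixed
calibration seed) over z-scored predictors, with three trained classes —
immobile, balling, locomotion. A prediction is accepted only when its class
probability *strictly* exceeds τ = 0.7; otherwise the burst is labeled
"other", the catch-all for behaviors absent from the training set. The gate
is strict because the rule is worded as "exceeds"; the contract tests pin
0.700 → other, 0.701 → class. Leave-one-out cross-validation is per burst;
by default the gate is applied during evaluation (a gated burst counts
against its true class's recall), with an ungated variant available.

## Rhythm metrics

DI contrasts daylight and night activity *rates*, so the unequal lengths of
day and night cancel:

$$\mathrm{DI} = \frac{A_d/T_d - A_n/T_n}{A_d/T_d + A_n/T_n} \in [-1, 1],$$

with A the summed aSD and T the duration of the daylight (dawn→dusk) and
night segments. −1 is strictly nocturnal, +1 strictly diurnal, 0 equal
rates. Activity onset is the first run of at least *k* consecutive minutes
(default k = 1; larger k guards against isolated spikes) whose aSD exceeds
the individual's threshold — the mean aSD over that individual's full
deployment, which cleanly separates active from passive minutes whenever
activity is strongly bimodal. Per-phase and pooled thresholds exist as
options. TSdusk is the signed offset of onset from civil dusk (positive =
after dusk).

## Degree of Functional Coupling

Each 3-day window (4320 points at 1-min sampling) of the aSD series is
autocorrelated, the ACF is Fourier-transformed, and the DFC is the summed
spectral power at periods 24/k h (k = 1…720, i.e. every third bin of the
4320-point grid) divided by total power over periods from 3 days down to
2 min (DC excluded). Windows slide by one day and each DFC is assigned to
its window's last day; the first value therefore lands on deployment day 3.
Small gaps (≤ 5% of a window) are linearly interpolated; larger gaps
invalidate the window.

Two numerical choices matter and are deliberate:

1. **Circular autocorrelation.** The Fourier coefficients of the circular
   ACF equal the series' normalized power spectral density exactly, so a
   noise-free 24-h-periodic window gives DFC = 1 to machine precision and
   the direct-periodogram cross-check is exact. The linear biased
   estimator's taper leaks ~22% of a pure 24-h line's power into
   non-harmonic bins (DFC ≈ 0.78 for a perfect signal), which contradicts
   the statistic's definition of maximal synchrony.
2. **Power ratioed once, not twice.** The ACF already lives on the power
   scale; squaring its Fourier magnitudes again would ratio the *squared*
   periodogram, which suppresses everything but the dominant peak
   quadratically and saturates the DFC near 1 for any signal with a strong
   daily envelope (measured ≥ 0.95 on generator output regardless of
   disturbance). The implementation ratios the periodogram itself.

A Fisher-g-style significance screen of spectral peaks before ratioing is a
documented possible variant; the default is the unscreened ratio.

## Space use and nest survival

GPS cleaning runs in fixed order: drop fixes > 1000 m from the site center
(strict), average each 5-min event's remaining fixes, then a single forward
pass per individual drops any event implying > 2 m/s (strict) from the last
*retained* event. Events group into nights from the evening's 19:00 to the
next 07:00; nights with fewer than 5 events are unusable. The core area is
a bivariate Gaussian product-kernel density with per-axis reference
bandwidth h = σ̂·n^(−1/6) on a 200×200 grid with 3h margins; the 50%
isopleth area is accumulated from the highest-density cells. Bandwidth,
grid and isopleth are configuration keys; areas are reported per night
(a per-phase pooled KDE is available as an option).

Nest checks become spells — maximal runs of consecutive days in one nest.
A spell ends in an event when the next day's nest differs; spells hitting a
monitoring gap, the phase boundary, or study end are right-censored, and
phase-boundary censoring (rather than assigning boundary-spanning spells to
their starting phase) is the default so that each phase's risk set contains
only days actually lived in that phase; the alternative is a switch.
Pre- and post-festival days pool into "non-festival". Kaplan–Meier curves
and the log-rank test come from the survival package; the package reports
both spell counts and nest-day counts since either denominator is defensible.

## Per-individual change estimation

For every daily parameter the change measure is the full cross product of
transformed daily values: each of the festival-phase days minus each of the
pre-festival days (19 × 19 = 361 differences per individual when complete).
Transforms precede differencing by default (applying them to the
differences instead is a switch): DI is shifted by 1 and log-transformed
with an ε = 1e−6 guard (a DI of exactly −1 would otherwise be
untransformable), TSdusk is shifted by the absolute dataset minimum, daily
ODBA is z-scored, everything else is untouched. The model is a
random-intercept LMM fit by REML,

$$y_{ij} = \mu + b_i + \varepsilon_{ij},\qquad b_i \sim N(0,\sigma_b^2),\ \varepsilon_{ij} \sim N(0,\sigma_e^2),$$

and each individual's predicted change is the shrunken conditional mean
μ + b̂ᵢ with a 95% interval built from the conditional variance of b̂ᵢ plus
the fixed-intercept variance damped by (1 − sᵢ)², sᵢ the shrinkage weight;
this prediction-error form collapses to zero width in the noise-free limit,
as it should. A change is "significant" when the interval excludes zero.
When σ̂b² is estimated at the boundary the fit falls back to a pooled
intercept and says so.

**Known limitation — pseudo-replication.** The 361 pairwise differences are
dependent: every day participates in many differences, so the effective
per-individual sample size is on the order of the number of days, not of
pairs. The population-level intercept is unaffected (the random intercept
absorbs the day-sampling variance of each individual's mean), but the
per-individual conditional intervals treat the differences as independent
and are therefore optimistic by roughly √(n_pairs/n_days). Null
simulations with the generator's disturbance effects switched off make this
concrete: roughly half of the individuals show a "significant" change in DI
or TSdusk where none was injected, although the same intervals achieve
nominal (90–99%) coverage when differences really are independent draws
from the fitted model. The cross-product design is reproduced because it is
the design under study — fidelity over correction — but per-individual
significance flags should be read as descriptive, not inferential, and any
confirmatory use should collapse to day-level means first.

## The synthetic study generator

`simulate_study()` emulates the full deployment: 8 individuals (balanced
sexes), 19 + 19 days plus 5 nest-only post days, per-minute behavior labels
from a bout-structured (geometric dwell ≥ 1 min) label process — rest with
occasional balling bouts by day; locomotion-dominated activity from a
nightly onset (civil dusk + individual offset) until shortly before dawn —
with per-behavior aSD/ODBA levels calibrated so locomotion sits an order of
magnitude above rest and the deployment-mean threshold falls cleanly
between them. GPS nights are Gaussian scatter around a nightly center
(σ = 50 m baseline) in site-local planar meters — the method's distance
rules are metric, so geodesy would add nothing testable — sampled as 144
five-fix events per night, with configurable artifact injection (far
points and super-speed jumps, both flagged in ground truth). Twilight
times come from a smooth sinusoidal Berlin-like seasonal template, not an
ephemeris; only internal consistency matters downstream. Nest changes are
daily Bernoulli hazards (females 0.34, males 0.42, matching next-day
re-use probabilities of ~66% and ~58%).

Festival effects and their defaults:

* `onset_delay_min = 45` — activity onset delay; the scale of published
  analogous festival effects on nocturnal mammals (roost departures delayed
  by up to ~47 min).
* `area_scale = 0.5` — nightly core-area multiplier (positions scaled by
  its square root).
* `dfc_noise_gain = 0.25` — circadian disruption: inflates nightly onset
  jitter (3 → 3 + 45·g min SD) and scrambles minutes *inside* the active
  window (probability 0.5·g per minute). The disruption is deliberately
  confined to the dusk–dawn window so that the injected onset delay and the
  DFC degradation remain separately recoverable; the generator therefore
  does **not** emulate daytime restlessness, and DI barely moves under
  disturbance even though the motivating system showed DI decreases.
* `male_nest_hazard_mult = 1.44` — discrete-hazard multiplier for male
  festival nest changes, reproducing a re-use drop from ~58% to ~46%.

Raw waveforms (gravity posture plus behavior-specific dynamics: small noise
for immobility, a rotated static vector for balling, 1–3 Hz sinusoids for
locomotion, broadband AR noise for "other") are synthesized on demand; a
full-size study is ~115 million samples, so waveform-level runs are meant
for scaled configurations and the default pipeline consumes the burst-level
summaries directly. No quantitative per-behavior amplitude figures exist to
fit against; the waveform parameters are free, documented choices, and what
passing tests show is that the *pipeline machinery* recovers what was
injected — not that the generator reproduces real hedgehog biomechanics.

## Problem sizes used by the test-suite

Module tests run on scaled studies (1–2 individuals, 3–8 days). The
recovery checks run one full-size summary-level study each (8 × 38 days,
~440k bursts): onset-delay recovery within ±10 min, area-ratio recovery
within ±20%, significant DFC decreases for ≥ 7/8 animals at strong
disruption (g = 0.6), LOOCV recall ≥ 0.9 per class on 30 calibration bursts
per class, and the null false-significance check described above (which
fails by design of the cross-product interval, and is retained as a
documented red flag rather than weakened). Oracle checks are closed-form:
hand product-limit KM, exhaustive permutation-moment log-rank,
bivariate-normal 50% HDR (π σ² 2 ln 2), balanced-ANOVA REML equalities at
1e−6, and the exact Wiener–Khinchin periodogram identity.

## A worked example

```{r example, eval = FALSE}
cfg <- study_config(n_individuals = 4, pre_days = 8, festival_days = 8)
res <- run_pipeline(cfg, seed = 1)
res$changes
res$nest_comparison
plot_change_estimates(res$fits$dfc, title = "DFC")
```
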