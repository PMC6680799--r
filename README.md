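# hoglog

Behavioral-disturbance analysis for bio-logged wildlife.

`hoglog` implements, as a tested and reusable R package, the complete
analysis pipeline of a multi-logger field design in which a small number of
free-ranging nocturnal animals (the motivating system is urban hedgehogs in
a city park) is monitored over a baseline phase and an acute anthropogenic
disturbance phase of equal length, and every individual's behavioral change
is quantified along several axes at once:

- **Accelerometry** — per-minute triaxial bursts (100 Hz, 2.5 s) are
  validated (≥ expected sample count), reduced to 25 predictors (per-axis
  mean, sd, inverse CV, variance, kurtosis, skewness, spectral weighted
  mean; cross-axis *q*, pitch, roll, ODBA), and classified into
  immobile / balling / locomotion by a multiclass RBF SVM whose prediction
  is accepted only when the class probability strictly exceeds 0.7
  (otherwise "other"). Evaluation is leave-one-out CV with per-class recall
  and precision.
- **Circadian metrics** — the diurnality index
  `DI = (A_d/T_d − A_n/T_n)/(A_d/T_d + A_n/T_n)` (−1 fully nocturnal, +1
  fully diurnal), activity onset (first run of minutes with aSD above the
  individual's deployment-mean threshold) and its signed offset from civil
  dusk (TSdusk), and daily ODBA sums under a ≥ 1430-of-1440 burst
  completeness filter.
- **Degree of Functional Coupling** — on 3-day moving windows of the
  per-minute aSD series, the share of spectral power on harmonics of the
  24-h day (periods 24/k h, tested from 3 days down to 2 min), computed
  through the autocorrelation; 1 = fully entrained, 0 = no daily
  structure.
- **Space use** — GPS cleaning (1000-m site radius, 5-min event averaging,
  strict 2 m/s forward speed filter), evening-anchored nights, and nightly
  50% kernel-density core areas (reference bandwidth σ̂·n^(−1/6)).
- **Nest survival** — daily nest checks become utilization spells;
  Kaplan–Meier curves and log-rank (Mantel) tests compare festival vs
  non-festival phases per sex.
- **Per-individual change** — for each daily parameter, all pairwise
  festival-minus-pre differences (19 × 19 per individual) feed a
  REML random-intercept model `diff ~ 1 + (1 | individual)`; each animal's
  predicted change is the shrunken conditional mean with a 95% interval,
  flagged significant when the interval excludes zero.

Because the motivating study's raw logger data are not deposited, the
package includes a **synthetic study generator** (`simulate_study()`) with
full ground truth — behavior-specific burst waveforms, nocturnal activity
schedules, GPS noise and artifacts, nest-change hazards, and configurable
disturbance effects (onset delay, area shrinkage, circadian disruption,
elevated male nest-change hazard) — so every stage is testable end to end.
See the methods vignette (`vignettes/hoglog-methods.Rmd`) for the model
details, numerical choices, and known limitations (notably the
pseudo-replication inherent in the pairwise-difference design).

## Worked example

```r
library(hoglog)
cfg <- study_config(n_individuals = 4, pre_days = 8, festival_days = 8)
res <- run_pipeline(cfg, seed = 1)
res$changes
```

```
          parameter n_individuals n_decrease n_no_change n_increase
1             kde50             4          4           0          0
2                di             4          0           0          4
3        tsdusk_min             4          0           0          4
4          odba_sum             4          1           3          0
5               dfc             4          3           1          0
6   budget_immobile             4          0           3          1
7    budget_balling             4          0           3          1
8 budget_locomotion             4          0           4          0
9      budget_other             4          2           1          1
```

Under the default disturbance effects all four simulated animals shrink
their nightly core area (`kde50`: 4 decreases) and delay their activity
onset (`tsdusk_min`: 4 increases — positive TSdusk means onset after civil
dusk), three of four show a significant drop in 24-h coupling (`dfc`), and
behavior budgets barely move, which is exactly what was injected. The
per-individual detail sits in `res$fits`, e.g.

```r
res$fits$kde50$estimates
```

```
  individual_id pred_change      ci_lo      ci_hi significant
1           H01  -0.5577989 -0.5888739 -0.5267239        TRUE
2           H02  -0.3155392 -0.3466142 -0.2844642        TRUE
3           H03  -1.0073121 -1.0383871 -0.9762371        TRUE
4           H04  -0.6410820 -0.6721570 -0.6100070        TRUE
```

(changes in hectares of nightly core area), and `res$nest_comparison`
holds the per-sex log-rank results. `plot_change_estimates(res$fits$dfc)`
draws the forest-style per-individual change plot.

A thin command-line wrapper over the same functions lives at
`inst/cli/hoglog.R`:

```sh
Rscript inst/cli/hoglog.R run --seed 1 --out out/ --individuals 4 --pre-days 8 --festival-days 8
```

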