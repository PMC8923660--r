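# saccmod

Microsaccade detection and attention-related modulation of spike trains.

`saccmod` is an R package for neurophysiology labs analyzing covert
spatial-attention experiments in which fixational eye movements (1 kHz eye
position) are recorded together with extracellular spike trains. Its
purpose is to answer a specific confound question: **is delay-period
attention-related modulation a genuine attentional signal, or a secondary
effect of microsaccades?** Every microsaccade is followed by a transient
suppression of firing, and microsaccade direction covaries with the
attended location, so naive condition averages mix the two.

## What it implements

* **Microsaccade detection** with the classic 2D velocity-threshold
  method: five-point moving-window velocity
  `v_n = (x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) / (6\,\Delta t)`,
  per-axis robust thresholds `η = λ·σ` with
  `σ = sqrt(median(v²) − median(v)²)` and `λ = 4`, the elliptical
  criterion `(v_x/η_x)² + (v_y/η_y)² > 1`, minimum duration 6 ms, and
  cue-relative classification (±90° window → "toward" vs "away").
* **Peri-event rate analysis**: spike counts in non-overlapping 20-ms
  bins, z-scored per unit (mean and population SD over all trials,
  conditions, and bins of the normalization span), aligned on patch onset
  or on individual microsaccade onsets.
* **The matching controls** that make microsaccade-conditioned comparisons
  fair: timing-matched subsampling (eight 100-ms bins over the 200–1000 ms
  delay period, a no-microsaccade condition defined by ±200 ms event-free
  windows around bin centers, every condition subsampled without
  replacement to the per-bin minimum) and 2D eye-position matching on a
  0.25° × 0.25° grid.
* **The statistical machinery**: balanced full-factorial fixed-effects
  ANOVA on unit-level cell means with Tukey–Kramer post hoc contrasts
  (`SE = sqrt(MSE/2·(1/n₁+1/n₂))`, studentized-range p-values), Wilcoxon
  rank tests, chi-square proportion tests, Clopper–Pearson intervals.
* **A synthetic-session generator** (task structure, fixational eye traces
  with minimum-jerk microsaccades, inhomogeneous-Poisson spike trains with
  attention and suppression terms, behavioral outcomes) with full ground
  truth, so detection, matching, and the ANOVA chain all have
  parameter-recovery and null-calibration tests.

The analysis surfaces mirror the standard figures of this literature:
delay-period modulation split by behavioral outcome, microsaccade
probability time courses and polar direction histograms,
microsaccade-conditioned hit rates and reaction times, the epoch
time-course analysis (five 100-ms epochs with trials classified by the
microsaccades they contain), the peri-microsaccadic before (−60–0 ms) /
after (40–100 ms) analysis on timing-matched data, a single-patch motor
control, and an eye-position-matched control.

## Worked example

```r
library(saccmod)
res <- run_pipeline(run_config(seed = 11, apply_screen = FALSE))
print(res)
```

```
Pipeline result
  10 sessions, 3520 trials, 17923 detected microsaccades
  units included by screen: 68 / 68
  epoch ANOVA d.o.f.: total 2039, error 2010
  config hash: 299fbf575f24e3fad57c66d1ed0b4dd3
```

Ten sessions (two subjects × five) were simulated, ~17,900 microsaccades
detected, and all 68 simulated units pass the responsiveness/modulation
screen. The epoch analysis feeds a 5 (epoch) × 2 (attention) × 3
(microsaccade condition) factorial with 68 values per cell — total
d.o.f. 2039, error d.o.f. 2010. The suppression and attention deltas
behave as the generative model dictates:

```r
aggregate(value ~ attention + microsaccade, res$perisaccadic$delta_suppression, mean)
```

```
   attention microsaccade       value
1  cue_in_rf         away -0.22997863
2 cue_out_rf         away -0.19931409
3  cue_in_rf         none -0.01977369
4 cue_out_rf         none -0.03829582
5  cue_in_rf       toward -0.22565333
6 cue_out_rf       toward -0.18428813
```

Normalized firing drops by ~0.2 z after microsaccades in either direction
but not in the timing-matched no-microsaccade condition — the saccadic
suppression signature, independent of the cue — while the attention
modulation (`res$perisaccadic$delta_attention`, ~0.12 z here) is present
before microsaccade onset in every condition. `run_pipeline(cfg, out_dir =
...)` writes all canonical CSV/JSON/YAML artifacts, stamped with the
configuration hash.

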