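---
title: "Dissociating attention-related modulation from microsaccades: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating attention-related modulation from microsaccades: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saccmod)
```

## The scientific problem

During covert spatial attention tasks, neurons whose response fields (RFs)
contain the attended stimulus fire at elevated rates during the sustained
"delay" period. Subjects also produce fixational microsaccades — small
(< 1°) involuntary saccades — whose direction covaries with the attended
location, and every microsaccade is followed by a transient suppression of
visually driven activity. This raises a confound: is the delay-period rate
elevation a genuine attentional state signal, or a secondary consequence of
microsaccade generation?

`saccmod` implements the analysis program needed to answer that question
from paired eye-tracking and spike data: detect microsaccades, z-normalize
peri-event firing, and then compare attention conditions *within*
microsaccade-controlled subsets of the data — epochs free of microsaccades,
data aligned on individual microsaccade onsets with the timing of events
matched across conditions, and eye-position-matched subsets. A synthetic
session generator with full ground truth makes every stage testable.

## The generative model

`simulate_session()` produces one session of a covert attention task:

* **Task structure.** Cued blocks of 70 two-patch trials with the cue side
  alternating between blocks; 18 single-patch trials before each block
  announce the new cued location (and double as the motor-control data
  set). Within blocks, the saturation change occurs at the cued vs the foil
  patch in a 3:1 ratio, uniformly 1–4 s after patch onset. The cue ring
  flashes for 133 ms, 500 ms before the patches. Responses (joystick
  release) are scored within 150–750 ms of the change. Times throughout the
  package are milliseconds relative to color-patch onset; bins are
  half-open `[a, b)`; angles are degrees, cue-relative angles wrapped to
  `(-180, 180]`.
* **Eye traces** (1 kHz) are a sum of an Ornstein–Uhlenbeck drift
  (diffusion 0.001 deg²/s, centering time constant 2 s), white tremor
  (SD 0.005°), and injected microsaccades with minimum-jerk displacement
  profiles. The minimum-jerk profile is smooth, biologically plausible, and
  has the analytic peak speed `1.875 A / D`, so a linear main sequence
  (peak speed = 100/s × amplitude) fixes the duration at ~19 ms.
  Microsaccade onsets follow a piecewise-constant hazard: 1.5 events/s at
  baseline, a near-zero dip (×0.05) for 150 ms after patch onset, and a
  rebound (×1.3) from 150–600 ms — the canonical post-stimulus rate
  signature. Amplitudes are log-normal (median 0.3°, truncated at 1°);
  directions relative to the cue are a mixture of toward and away lobes
  (wrapped normals, SD 30°) plus a uniform component, weighted
  0.25/0.25/0.5. The amplitude and main-sequence values are conventional
  for fixational saccades in the primate literature; the source study
  reports no amplitude statistics, so these are the package's own choices,
  not reproduced values.
* **Spike trains** are inhomogeneous-Poisson draws (thinning algorithm —
  exact and simple) from per-unit rate functions: baseline (10–25 sp/s
  across units), an exponentially decaying visual transient when a patch
  is in the RF (peak 50 sp/s, latency 45 ms, decay 80 ms), a sustained
  attention increment when the cue is in the RF (+4 sp/s from 200 ms), and
  a suppressive episode after every true microsaccade (latency 20 ms,
  duration 60 ms). Suppression is multiplicative (rate × 0.5) by default;
  an additive mode exists specifically so the "modulation passes through
  suppression unchanged" prediction has an exact generative counterpart.
  An optional pre-microsaccadic bias term (rate increment before
  RF-directed events) lets the motor control analysis be validated against
  a known motor signal, and `miss_delta_scale` couples the attention
  increment to the behavioral outcome so the hit/miss modulation
  comparison is testable.
* **Behavior.** Hits occur with probability 0.83 on cue changes (false
  alarms 0.05 on foil changes); reaction times are truncated normal
  (400 ± 80 ms) with an optional +30 ms penalty when a microsaccade away
  from the cue lands within ±50 ms of the change — giving the
  microsaccade-conditioned behavioral analyses a recoverable effect.

The defaults describe the study conditions: two subjects × five sessions,
34 units per subject (RF side alternating across units), four blocks per
session — 68 units and ~3,500 trials in total. Everything is deterministic
given the master seed; per-session seeds are derived from it.

What the generator does *not* emulate: cue-ring-evoked visual transients,
saturation-change-evoked responses, non-Poisson spiking statistics
(bursting, refractoriness), drift in unit isolation, blinks, and binocular
disparity. Passing tests therefore certify the pipeline's correctness and
calibration on data with these simplifications, not the neurophysiology of
any particular recording.

## Microsaccade detection

`detect_microsaccades()` implements the standard two-dimensional
velocity-threshold method. Velocity is a five-point moving-window
derivative (`v_n = (x[n+2] + x[n+1] - x[n-1] - x[n-2]) / (6 dt)`); the two
boundary samples at each end are invalid. Per-axis thresholds are
`eta = 4 × sigma`, where `sigma = sqrt(median(v²) - median(v)²)` is the
median-based robust SD of the velocity noise. Samples with
`(vx/eta_x)² + (vy/eta_y)² > 1` (elliptical criterion) form candidate
runs; runs shorter than 6 ms are rejected, and surviving runs separated by
less than 20 ms are merged.

Two ordering/screening choices deserve note, since the published method
leaves them open:

* **Duration filter before gap merge.** Merging first lets scattered one-
  or two-sample noise crossings accumulate into ≥ 6 ms pseudo-events
  (measured ~0.8 false events/s at the default noise level); filtering
  first yields recall 1.0 with ≤ 1 ms median onset error and essentially
  zero false positives on event-free traces, while the merge still
  suppresses double detection of dynamic overshoots of real saccades.
* **Automated surrogate for manual screening.** Rather than visual
  verification of every event, the package rejects events larger than 2°
  (configurable). Neither rule claims to reproduce the original manual
  screening.

A direction exactly at ±90° relative to the cue is a measure-zero
tie-break: −90° is labeled toward, +90° away, so each label covers exactly
half the circle and cue-side flips map the labels onto each other.

## Normalization and alignment

Spike counts are binned in non-overlapping 20-ms windows. Each unit is
z-scored with the mean and *population* SD of its binned counts pooled
across all trials, conditions, and bins of the normalization span — by
default −100 to 1000 ms around patch onset, covering baseline, transient,
and delay. The span is not fully specified in the source study, so it is
exposed in configuration and stored in every normalized object's
provenance. Event-aligned matrices re-bin the raw spike times relative to
each alignment time and reuse the unit's stored constants, so all rates
share one normalized scale; alignment windows that exceed a trial's
recorded span drop the event with a count of the exclusions. Window means
average only bins lying fully inside the half-open window.

Units enter analyses if they pass `screen_units()`: visual responsiveness
(counts 50–150 ms after patch onset vs −100–0 ms baseline, two-sided
rank-sum p < 0.01, required on both two-patch trials and single-patch
trials with the patch in the RF) and attention modulation (delay-period
rate, cue-in-RF > cue-out-of-RF, two-sided rank-sum p < 0.01 plus the sign
requirement — which makes the null pass rate α/2).

## The matching controls

`timing_match()` makes microsaccade-aligned comparisons fair: the 200–1000
ms analysis window is tiled with eight 100-ms bins; per bin it counts
alignment candidates for every condition — toward and away events (per cue
side) by onset bin, and, for the no-microsaccade condition, trials with no
detected event within ±200 ms of the bin center, the center standing in as
the alignment time — then subsamples every condition *without replacement*
to the per-bin minimum. Post-match per-bin counts are exactly equal across
conditions, asserted on every run. Whether a trial contributing several
events to one bin counts once or per event is unstated in the source;
both modes are implemented (`mode = "event"` default, `"trial"`
alternative) and recorded in provenance. A single seeded generator,
consumed in condition-then-bin order, makes selections reproducible.

`eye_position_match()` applies the same minimum-count scheme on a spatial
grid: per-event average eye position in the −60–0 ms window, binned at
0.25° × 0.25°, equalized across conditions per spatial cell — removing
pre-microsaccadic eye-position differences as an explanation for
condition differences.

## Analysis surfaces and the factorial ANOVA

All headline analyses reduce to unit-level cell means feeding balanced
full-factorial fixed-effects ANOVAs (all interactions, neuron identity not
a factor), with Tukey–Kramer post hoc contrasts
(`SE = sqrt(MSE/2 (1/n₁ + 1/n₂))`, p from the studentized-range
distribution with the full interaction's group count and the error
degrees of freedom; at equal n this is Tukey's HSD). With 68 units the
designs give total/error degrees of freedom of 2039/2010 (five epochs ×
two attention × three microsaccade conditions), 815/804 (before/after ×
attention × microsaccade), 407/402 (the two delta ANOVAs and the motor
control), and 543/536 (the eye-position-matched control, whose
microsaccade factor has two levels). Sums of squares are sequential, which
on balanced data equals every other type; unbalanced input is rejected
unless explicitly allowed. Degrees-of-freedom identities
(`total = N − 1`, `error = total − Σ term`) are asserted on every fit.

* **Epoch analysis**: per epoch (200–300, 350–450, 500–600, 650–750,
  800–900 ms), trials are classified by the events inside the epoch —
  none / toward / away; trials containing both directions are excluded
  and counted, an explicit choice where the source is silent — and
  normalized rate is measured in the 100 ms immediately after the epoch
  (alternative measurement offsets are a parameter, not a separate code
  path). Note the "none" rule here (no onsets inside the epoch itself) is
  deliberately weaker than the ±200 ms rule of the timing-matched control;
  the two live in different configuration objects and are never mixed.
* **Peri-microsaccadic analysis**: runs only on timing-matched sets
  (matching provenance is mandatory), measuring before (−60–0 ms) and
  after (40–100 ms) windows, then `delta_attention` (cue-in − cue-out per
  window) and `delta_suppression` (after − before per cue condition), each
  with its own two-factor ANOVA, plus the companion average eye-speed
  trace that verifies the alignment.
* **Motor control**: single-patch trials with the patch opposite a unit's
  RF (no stimulus in the RF), events relabeled relative to the RF,
  same timing-matched before/after pipeline.
* **Behavior**: hit rates with Clopper–Pearson 95% intervals and
  chi-square proportion tests (no continuity correction), reaction-time
  comparisons (hits only — the source leaves this open, so the choice is
  labeled) with two-sided rank-sum tests, conditioned on microsaccades
  within ±50 ms of the change.
* **Outcome split**: per-unit delay-period modulation computed separately
  for hits and misses, compared with a paired signed-rank test across
  units.

Rank tests use the exact distribution when feasible (no ties, fewer than
50 values) and the continuity-corrected normal approximation otherwise.

## Numerical choices and degenerate inputs

Population (divide-by-n) SD for z-scores; units with zero count variance
are excluded with a logged reason. Degenerate velocity traces (zero robust
SD) raise an error naming the trial. Empty matching bins contribute no
selections and are logged, not errors. All-tied rank tests return p = 1
with a warning. The studentized-range tail probabilities come from R's
`ptukey`, the reference numerical implementation of that distribution.
Seeds: every stochastic stage takes an explicit integer seed; stage seeds
derive from one master seed and stay below 2³¹ − 1.

## Calibration results and known limitations

The test suite calibrates the chain under the generator's null
(no attention increment, no microsaccade–rate coupling):

* the unit screen's attention component passes at its nominal α/2;
* the epoch ANOVA + Tukey–Kramer chain, run with `equalize_trials = TRUE`
  (every cell mean built from the same number of trials, the
  homoskedasticity condition under which the studentized range gives exact
  family-wise coverage), has an all-pairs family-wise error at the nominal
  5% over 500 spike-redraw replicates.

One measured limitation is worth stating plainly: applying the *all-pairs*
studentized-range family to unit-level cell means built from unequal trial
counts is anticonservative (family-wise error near 0.3 in the same null
simulations), because a "none" cell averages roughly ten times more trials
than a direction cell, and pooled-MSE studentization understates the SE of
direction-cell pairs. The package therefore reports contrasts between
cells sharing a trial-count structure, where the equal-variance assumption
holds; arbitrary cross-cell contrasts are possible via `tukey_kramer()`
but inherit this caveat. Other limitations: fixed-effects only (no
hierarchical alternative), no blink or binocular handling, and the
generator simplifications listed above.

Problem sizes used by the automated checks are the package's own choices:
the full study scale (68 units, ~3,500 trials) for degrees-of-freedom
arithmetic and parameter recovery; 1,000 three-second traces for detection
oracle equivalence; 100 randomized scenarios for matching invariants; 500
scaled-down replicates (one session, four units) for null calibration.

## A worked example

```{r example, eval = FALSE}
cfg <- run_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "run1")
res$epoch$anova          # 5 x 2 x 3 factorial, d.o.f. 2039 / 2010
res$perisaccadic$delta_suppression |> head()
```

See the README for the full worked example with printed output, and
`scripts/acceptance.R` for the script that recomputes every headline
quantity from scratch.
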