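---
title: "Validating wearable heart-rate monitors under dynamic conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating wearable heart-rate monitors under dynamic conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Wrist-worn wearables estimate heart rate (HR) optically by
photoplethysmography (PPG), and their accuracy is known to degrade when HR
changes rapidly — at activity onset, load changes and abrupt stops — which
is exactly when stress- and health-monitoring applications need them most.
Method-comparison studies therefore validate device streams against a
reference (ECG or a chest strap) over a phased activity protocol, and
separate *transient states* (windows around protocol phase changes) from
*steady states* (everything else).

`hrvalid` implements that study design end to end as reusable, testable
code:

1. a **protocol** representation with derived transition windows and
   timestamp labelling;
2. a **synthetic cohort generator** producing a 1 Hz ground-truth reference
   per subject plus device streams corrupted by realistic observation
   models;
3. **pairing** of reference and device streams at three resolutions with
   pairwise deletion and missingness accounting;
4. **agreement and accuracy statistics**: per-participant MAE/MAPE,
   repeated-measures concordance (rmCCC), repeated-measures Spearman
   correlation on ranks, and Bland–Altman bias and 95% limits of agreement
   via a linear mixed model;
5. paired **Wilcoxon signed-rank comparisons** between devices and between
   conditions with Bonferroni control;
6. an orchestrating **pipeline** (`run_validation()`) with table, manifest
   and figure output, plus a small CLI under `inst/cli/`.

## The protocol and transient-state segmentation

The default protocol (`build_default_protocol()`) is a 20 min, six-phase
treadmill sequence: sit 3 min, stand 3 min, walk 4 km/h 4 min, walk 6 km/h
4 min, walk 6 km/h at 5% incline 4 min, stand 2 min. Phase boundaries fall
at 180, 360, 600, 840 and 1080 s, and each defines a transition window
from 10 s before to 60 s after the onset (`derive_transitions()`,
configurable spans). Labels come from the predefined protocol timing
applied identically to every subject — no event detection from the signal
itself, which keeps the segmentation deterministic and comparable across
devices.

Numerical conventions, chosen where the design was genuinely open:

* **Window bounds are closed on both ends.** This keeps samples at exactly
  `onset − 10` and `onset + 60` in-window for every reporting frequency; at
  1 Hz each window holds 71 samples.
* **Overlapping windows** (impossible for the default spans, where gaps are
  at least 120 s) assign a sample to the earlier-onset window, with a
  warning.
* **Timestamps** are integer seconds from protocol start; ISO 8601 input is
  converted against a configured start time and floored to whole seconds.

## The generative model of the synthetic cohort

The generator exists to give the statistics something with the right
*structure*: subject heterogeneity, a shared time-varying trajectory,
autocorrelated variability, device-specific reporting schedules, and error
that worsens during transitions. Per subject, the reference trajectory is

* a first-order relaxation `dHR/dt = (target(phase) − HR)/tau` towards a
  load-specific target, integrated exactly between 1 Hz samples — the
  simplest dynamics that reproduce the rise/plateau morphology of HR during
  stepwise exercise (`tau` defaults to ~35 s, drawn per subject from
  18–55 s, matching typical HR on-kinetics for light-to-moderate load);
* an additive orthostatic pulse `amp · exp(−(t − t1)/20 s)` at the
  sit→stand onset, emulating the sharp peak that wrist devices tend to
  miss;
* stationary AR(1) heart-rate variability (default SD 2.5 bpm, lag-1
  coefficient 0.8). The autocorrelation matters: with white noise,
  per-second and 10 s-averaged errors would differ only trivially, and the
  resolution comparison the pipeline performs would be vacuous.

Population defaults: resting HR ~ Normal(70, 8²) bpm truncated to
[50, 95]; steady-state increments per load step drawn from truncated
normals so targets are nondecreasing in load. A cohort of 24 subjects at
1 Hz over 1200 s yields 28,800 expected reference samples.

Device streams (`simulate_device()`) corrupt the reference through: a
reporting schedule (fixed-interval, minute, or jittered with integer gaps
from a shifted log-normal calibrated to a min/max/mean — only range and
average are typically published for commercial devices); a trailing-mean
`lag_window` emulating on-device smoothing and algorithmic delay; additive
bias; Gaussian read noise whose SD switches from `noise_sd_steady` to
`noise_sd_motion` inside transition windows (motion artefacts); per-sample
and burst dropout; and optional integer rounding. The six shipped profiles
(`default_device_profiles()`) span the reporting behaviours seen in
practice: a 1 s chest-strap-like device, a 1–3 s wrist device, two
irregular ~10 s wrist devices, a 60 s reporter with conservative motion
rejection, and a 1 s wrist device with heavy motion noise.

All randomness flows from one root seed through per-(subject, device)
derived streams, so adding a profile never perturbs existing series and
CSV export is byte-identical for identical inputs.

**What the generator does not emulate:** waveform-level PPG/ECG synthesis,
beat detection, skin-tone or placement covariates, per-subject protocol
deviations, and any particular vendor's proprietary algorithm (device
processing is undisclosed for commercial hardware; the corruption model is
a stylized stand-in). Passing tests on synthetic cohorts therefore show
that the *statistical machinery* behaves correctly under the assumed error
structure — not that any physical device meets a threshold.

## Pairing resolutions and missingness

Reference timestamps always drive the pairing; the device never defines
the grid.

* `pair_per_second()`: intersection of integer-second timestamps, no
  averaging.
* `pair_trailing_window()` (default 10 s): for each reference timestamp
  `t`, the device value is the mean over the half-open window
  `(t − 10, t]`. Half-open prevents a sample at exactly `t − 10` from
  being double-counted across consecutive reference ticks.
* `pair_synchronized_windows()` (default 60 s): both sides averaged over
  consecutive `[k·60, (k+1)·60)` bins anchored at protocol start —
  anchoring at t = 0 is reproducible and subject-independent.

A pair is dropped whenever either side is empty (pairwise deletion,
never imputation; outliers are retained). Steady/transition labels attach
at the reference timestamp for the per-second and 10 s datasets; 60 s
pairs carry no state because a 60 s average cannot resolve a 70 s
transient window — the pipeline enforces this (`validation_config()`
rejects transition analyses restricted to `sync_60s`).

Missingness is `1 − n_paired / n_expected`, with `n_expected` the count
of reference timestamps (or reference-occupied bins) across subjects with
a valid recording for that device.

## Agreement statistics

**Accuracy.** MAE and MAPE are computed per participant (MAPE denominator
is the reference value of each pair), then summarised across participants
as median and IQR using type-7 (linear-interpolation) quantiles —
configurable via `quantile_type`. Every retained participant counts
equally regardless of pair count.

**rmCCC.** Lin's concordance penalizes both poor correlation and
location/scale shift; the repeated-measures version must additionally
respect that observations cluster within subjects. We fit the stacked
long data by REML with a fixed method effect, a random intercept per
subject and a random intercept per paired observation:

```
value ~ method + (1 | subject) + (1 | pair)
rmCCC = (s2_subject + s2_pair) / (s2_subject + s2_pair + s2_resid + d^2/2)
```

The pair effect carries the HR trajectory shared by both methods at each
timestamp, so shared physiological variation counts as agreement and only
method disagreement (plus the squared fixed offset `d`) is penalized.
This was the main genuinely open design choice: a subject-intercept-only
model pushes the entire within-subject trajectory into the residual and
yields concordances near 0.2 even for a practically perfect 1 Hz chest
device, which neither matches the estimator's intent nor the magnitudes
such devices produce in validation studies. With one pair per subject the
pair and subject terms coincide; the redundant subject term is dropped
and the estimator reduces *exactly* to the closed-form Lin's CCC (a
property the test suite asserts to 1e-6). Confidence intervals are
percentile bootstrap over subjects (seeded; default 1000 resamples; the
pipeline exposes `n_boot`, and CIs can be skipped with `n_boot = 0`).

**rmSCC.** Spearman association with subject clustering: both variables
are ranked across the pooled sample, then the repeated-measures
correlation (subject-centred ANCOVA common slope, i.e. subject fixed
intercepts with a shared slope, correlation from the sequential
sums of squares) is applied to the ranks.

**Bland–Altman.** Differences `d = dev − ref` are modelled as
`d_ij = mu + u_i + e_ij` with subject random intercepts (REML). Bias is
`mu_hat` with a Wald test against zero; the 95% limits of agreement are
`mu_hat ± 1.96·sqrt(s2_u + s2_e)`, the interval expected to cover 95% of
individual differences across subjects and repeats. When the subject
variance hits the boundary at zero, the limits reduce to the ordinary
pooled-SD form and a warning is raised. Degenerate all-equal differences
return `[c, c]` directly. Proportional bias is left to visual inspection
of the Bland–Altman plot (`plot_bland_altman()`), not modelled.

**Thresholds.** Median MAPE ≤ 10% *or* median MAE ≤ 5 bpm is
"acceptable" (the cardiac-monitor readout-error standard: ±10% of input
rate or ±5 bpm, whichever is greater); correlation bands are weak
(CC ≤ 0.5), moderate (0.5–0.7), strong (CC ≥ 0.7), with a stricter
acceptability boundary at 0.80. Boundaries are inclusive as printed.

## Hypothesis tests and multiplicity

Device-versus-device and steady-versus-transition comparisons use paired
two-sided Wilcoxon signed-rank tests on per-participant MAPE, aligned by
subject and pairwise-complete per comparison. Zero differences are
dropped (classic convention; the count is reported), the exact null
distribution is used for n ≤ 25 without ties among |d| (the switch point
is configurable), and a continuity-and-tie-corrected normal approximation
otherwise. All k(k−1)/2 unordered device pairs are tested with a
Bonferroni-adjusted level α/k(k−1)/2 — 21 comparisons and α = 0.0024 for
seven devices, 15 and α = 0.0033 for six. Pairs with fewer than five
usable subjects are flagged untestable rather than tested badly.

## The pipeline

`run_validation()` composes the stages and produces, per device and
resolution: missingness, accuracy, agreement, threshold verdicts;
steady/transition and per-transition accuracy with condition tests at the
fine resolutions; pairwise comparison matrices; a tidy results table; a
JSON manifest (hash-stable for identical config and seed — figures are
deliberately excluded from the determinism contract); and optional
Bland–Altman and notched-boxplot figures.

Devices whose pair count at a resolution falls below
`min_pair_ratio × median` pair count (default 0.25) are excluded from
that resolution's statistics with an audit log entry — a minute-interval
reporter simply cannot be validated second-by-second, and including it
would distort the comparison matrices.

## Problem sizes and numerical checks

The test suite regenerates all fixtures in code. Simulation-based checks
use sizes chosen to balance statistical resolution against a laptop-scale
run: pairing is verified against a brute-force O(n·m) oracle on 100
random series; exact Wilcoxon p-values against full 2^n enumeration for
n ≤ 12; Bland–Altman recovery over 50 replicates of 24 subjects × 100
pairs (bias 2 bpm, subject SD 1, residual SD 3); the resolution and
condition contrasts over 50 seeded cohorts of 24 subjects; and type-I
error of both tests over 500 null cohorts each (a few hundred replicates
are needed before a binomial rejection-rate estimate is meaningfully
narrower than the 3–7% acceptance band around the nominal 5% level).

## Known limitations

* The corruption model is stylized; real PPG error is signal-dependent
  (motion spectra, perfusion, contact pressure) in ways a
  Gaussian-with-regime-switch model does not capture.
* rmCCC on real data depends on the exact repeated-measures estimator
  chosen; different defensible choices (e.g. subject-only random effects,
  U-statistic estimators) give different values, so cross-study numeric
  comparisons should name the estimator.
* The Wald test for the Bland–Altman bias relies on the normal
  approximation of the fixed-effect estimate; with very few subjects a
  Satterthwaite or bootstrap test would be preferable.
* Lag correction is out of scope: pairing aligns by timestamp only, so a
  device with a long internal delay is penalized as inaccurate rather
  than late — which mirrors how such devices behave in applications that
  consume their timestamps at face value.
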