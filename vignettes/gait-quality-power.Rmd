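---
title: "Daily-life gait quality as a trial outcome: models, characteristics, and sample size"
author: "gaitquality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Daily-life gait quality as a trial outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitquality)
```

## The problem this package addresses

Falls-prevention trials in older people usually rely on fall counts over
6--12 months of follow-up. Characteristics of gait measured during daily
life with a single trunk-worn accelerometer -- stability, regularity,
symmetry, smoothness, intensity, complexity -- are associated with fall
risk and can be read out immediately after an intervention, which makes
them attractive trial outcomes. Planning such a trial requires two
ingredients this package computes end to end:

1. **gait-quality characteristics** from raw tri-axial locomotion
   episodes, aggregated to one weekly median per subject;
2. **variance components** of those weekly values across two measurement
   weeks, feeding a **repeated-measures sample-size calculation**.

Because raw daily-life accelerometry is rarely shareable, the package
also contains two seeded synthetic generators -- one at the signal level
and one at the cohort level -- so that every stage can be exercised
against known ground truth.

## Signal model of the generator

`simulate_gait_episode()` builds gait-like tri-axial acceleration (g
units, 100 samples/s by default, clipped to the +/-6 g range of typical
sensors). One stride comprises two steps, and the spectral signature of
symmetric bipedal gait is imposed by construction: vertical (VT) and
anteroposterior (AP) channels are cosine sums at multiples of the *step*
frequency, the mediolateral (ML) channel at multiples of the *stride*
frequency. An `asymmetry` parameter leaks ML fundamental power to the
step frequency, emulating left-right asymmetric gait. Gravity (1 g) is
added to VT, and a yaw/pitch/roll misalignment rotation is applied last
so that realignment can be tested against a known truth.

All channels share one stride phase that accumulates a Gaussian
random-walk increment per stride (`phase_jitter_sd`, radians/stride,
interpolated linearly within strides). This single knob spans perfectly
periodic to strongly irregular gait. Its measured effect on the
characteristics (fixed-seed ladders at 0, 0.2, 0.5 rad/stride):

* stride regularity decreases strictly and local divergence rate
  increases strictly -- these two track the knob reliably;
* sample entropy rises from the periodic baseline but **saturates**
  above roughly 0.2 rad/stride: a pure phase perturbation keeps the
  signal locally smooth at 100 samples/s, and SampEn(m = 2, r = 0.2 SD)
  on oversampled smooth signals responds mainly to additive noise. Tests
  therefore assert only the periodic-vs-jittered ordering for SampEn,
  with additive noise switched off in the ladder fixtures;
* the index of harmonicity *increases* slightly with jitter: phase
  diffusion broadens the k-th harmonic in proportion to k, so the
  narrow (+/-0.1 Hz) integration windows lose high-harmonic power
  faster than fundamental power. A lower IH should not be read as
  "more phase-jittered" under this generator.

What the generator does **not** emulate: turning, stair climbing,
non-gait activity, realistic waveform shape (it is a harmonic
caricature), sensor drift, or amplitude variability between strides.
Passing tests on synthetic episodes therefore demonstrate correctness of
the *computations*, not clinical validity on real recordings.

## Realignment

Sensor axes rarely coincide with anatomical axes. `realign_axes()` uses
the standard two-stage approach: the episode-mean acceleration (gravity,
during upright walking) is rotated onto the vertical axis by the minimal
rotation; the residual horizontal-plane (yaw) angle is the one
minimising ML power at the detected step frequency, since left-right
symmetric gait concentrates ML power at stride, not step, frequency.
The yaw objective is a sinusoid in twice the angle, so a coarse
half-degree grid scan followed by golden-section refinement finds the
minimiser; of the two equivalent minimisers (period pi) the smaller
absolute angle is returned. A flat objective (no step-frequency power)
leaves yaw at zero with a warning; an episode-mean far below 1 g (free
fall, non-wear) is an error. Gravity, taken as the mean-vector
magnitude, is subtracted from VT afterwards.

With asymmetric gait the anatomical ML axis itself carries
step-frequency power, so the recovered yaw minimises the objective
rather than exactly reproducing the applied misalignment; tests compare
against an exhaustive grid-scan oracle in that case.

## The characteristics

All characteristics are computed on consecutive non-overlapping 10 s
epochs (configurable via `feature_config()`), after realignment:

* **Step/stride frequency** (`detect_frequencies()`): step frequency is
  the VT+AP periodogram peak in 1--4 Hz (a band covering older-adult
  cadence); stride time is the highest unbiased-autocorrelation peak
  within +/-25% of two step periods, refined by parabolic
  interpolation. An epoch whose stride-lag autocorrelation stays below
  0.2 is flagged non-gait: a bare "positive peak" criterion would
  accept about half of all white-noise epochs by chance, while genuine
  gait sits far above 0.2.
* **Walking speed and stride length**: inverted-pendulum estimate. VT
  acceleration (m/s^2) is band-passed (0.1 Hz to three times the step
  frequency) and doubly integrated in the frequency domain; `h` is the
  mean per-step peak-to-peak vertical excursion; step length is the
  chord `2 sqrt(2 l h - h^2)` for leg length `l` (default 0.9 m, used
  with a warning when not supplied); speed is step length times step
  frequency.
* **Dispersion**: per-axis SD and range, in m/s^2 by default (a `units`
  switch selects g).
* **Stride regularity**: unbiased (lag-corrected) autocorrelation at
  the stride lag, local maximum within +/-10% of that lag, clamped to
  [-1, 1].
* **Dominant spectral peak**: Welch spectrum (Hann window, 5 s
  segments, 50% overlap) normalised to unit power. Amplitude is the
  power fraction in the dominant peak's main lobe (contiguous bins
  above a tenth of the peak power -- below the Hann side-bin level of a
  pure tone, above the broadband floor); width is the half-power span
  in Hz.
* **Index of harmonicity**: power at the fundamental divided by the
  summed power of the first six harmonics, each integrated over
  +/-0.1 Hz; the fundamental is the step frequency for VT/AP and the
  stride frequency for ML.
* **Harmonic ratio**: spectral amplitudes at the first 20 stride
  harmonics; even/odd for VT and AP, odd/even for ML; capped at 100
  with a warning when the denominator is at machine precision.
* **Local divergence rate** (per stride): Rosenstein-style estimate
  with delay embedding (dimension 5, delay 10 samples), nearest
  neighbour excluding temporally close points (one stride), mean log
  divergence over half a stride, least-squares slope. Distances are
  floored at 1e-12 so an exactly periodic signal gives a flat curve
  rather than log-of-rounding noise.
* **Sample entropy**: SampEn(m = 2, r = 0.2 SD), Chebyshev distance,
  self-matches excluded, computed on the ML axis by default.
* **Composite score**: weighted sum of standardized stride-frequency
  autocorrelation, power at step frequency, overall RMS acceleration,
  and index of harmonicity. The original weighting scheme for this
  composite lives in external code and is not published as numbers, so
  the package deliberately does not guess: weights and standardization
  constants are supplied via `composite_weights()`, and the pipeline's
  default is an equal-weight composite standardized by cohort means and
  SDs. Both a normalised power fraction (`dominant_amp_vt`) and
  absolute spectral power are computable for the "power at step
  frequency" input; the power-fraction is the default mapping.

`extract_features()` runs the whole set per epoch; invalid epochs are
flagged, never dropped, and per-epoch failures are collected into a
report attached to the result.

## Weekly aggregation and the variance-component model

`weekly_median_table()` reduces epoch rows to one weekly median per
subject and characteristic, with a configurable minimum number of valid
epochs per cell (default 10; no published wear-time criterion exists, so
the threshold is explicit). Two-week analyses use complete cases.

The weekly value of subject *i* in week *j* is modelled additively:

x_ij = mu + b_i + u_ij + e_ij,

with independent Gaussian between-subject (variance s2_BS),
within-subject/week (s2_WS) and sampling-error (s2_E) components.
`variance_components()` estimates them by the balanced two-way
method of moments: `s2_BS = max(0, (MS_subject - MS_error)/2)`, the week
effect is tested as `F = MS_week/MS_error` on (1, n-1) degrees of
freedom, and the between-week Pearson correlation is reported. The
expected correlation equals the between-subject share
`s2_BS / (s2_BS + s2_WS + s2_E)` (`implied_between_week_correlation()`).

**Separating s2_WS from s2_E.** With only two weekly values per subject
the decomposition identifies `MS_error`, which pools genuine
week-to-week change with the sampling error of the weekly median; the
two are not separately identifiable. The package makes the extra
information explicit: when day-level values are supplied, the sampling
variance of each weekly median is estimated and subtracted
(`s2_WS = max(0, MS_error - s2_E)`), and the result is flagged
`separable_error = TRUE`; otherwise the pooled value is reported as
`s2_E` with `s2_WS = 0` and the flag off. The sample-size formula below
needs only the total and between-subject variances, so the split never
affects it.

Two estimators of the weekly median's sampling variance are provided.
The default (`method = "moment"`) multiplies the unbiased
within-subject-week day variance by the variance factor of a K-point
median of standard normals, obtained once per K by seeded Monte Carlo
(`median_var_factor()`, 100,000 draws) -- the same factor the cohort
generator uses for calibration, making the estimator consistent under
the generator's own model (Gaussian day noise). A seeded 200-resample
bootstrap (`method = "bootstrap"`) is also available but is biased
upward by roughly 30% at 7 days per week (measured by simulation), which
is why it is not the default; the bias shrinks with more days.

Negative method-of-moments estimates are truncated at zero and always
flagged. An optional REML cross-check against a mixed model is part of
the test suite, not of the estimator.

## Sample size for a paired pre/post design

`required_n()` solves, for the smallest integer n >= 2,

n >= 2 s_S^2 (1 - r s_BS^2 / s_S^2) (t_{n-1,1-beta} + t_{n-1,1-alpha/2})^2 / Delta^2,

where s_S^2 is the total variance, s_BS^2 the between-subject variance,
r the assumed within-subject (pre/post) correlation, and Delta the raw
effect size. Cohen's d standardizes by the total SD, Delta =
d sqrt(s_S^2), which makes the calculation scale-free: only the
between-subject share rho = s_BS^2/s_S^2 matters. Both t-quantiles use
n - 1 degrees of freedom as written. Defaults are alpha = 0.05
(two-sided) and power 0.8; `sample_size_grid()` evaluates the full
d-by-r grid (defaults d in {0.3, 0.5, 0.8}, r in {0.3, 0.6, 0.9}).

Numerical notes, all oracle-tested:

* the right-hand side decreases in n, so "smallest n with n >= f(n)" is
  well defined; a naive fixed-point iteration can oscillate at small n.
  The search starts from the normal-quantile closed form and scans
  outward; the scan result exceeds the closed form by at most ~2--3
  (the t-correction contributes close to two participants across a wide
  range of n, plus ceiling rounding);
* at 1 degree of freedom the t-quantiles explode, which is why tiny
  problems resolve to n = 3 rather than 2;
* the t-correction inflates small-n cells relatively more, so
  n(d = 0.3)/n(d = 0.8) falls below the nominal (0.8/0.3)^2 = 7.11 by
  up to ~17% when the large-effect cell is small;
* with r = 0 the between-subject share is irrelevant, and scaling both
  variances by any positive constant leaves n unchanged.

Published variance-component estimates for 18 daily-life gait
characteristics in community-dwelling older adults (two one-week
measurement periods) are bundled as presets
(`gait_variance_presets()`), both as realistic generator parameters and
as ready inputs for the grid. Users reproducing published sample-size
tables for these characteristics should note that printed tables in the
literature do not always follow the total-SD standardization above; this
package documents its convention in every output rather than
reverse-fitting any particular table.

## Cohort generator and calibration

`simulate_cohort()` draws the additive model directly. With
`days_per_week = K > 1` the error component enters through day-level
values whose noise SD is `sqrt(s2_E / c_K)`, where `c_K` is the
Monte-Carlo variance factor of a K-point normal median -- so the weekly
median has sampling variance exactly s2_E by construction. Monte Carlo
is used instead of the asymptotic pi/(2K) factor because the asymptotic
value is poor at realistic day counts (c_7 is about 0.211 against the
asymptotic 0.224). An optional additive week-2 shift simulates an
intervention effect for power experiments. Components are Gaussian
throughout; heavy-tailed day noise is a known limitation.

## Problem sizes and determinism

Everything stochastic is seeded: generators take explicit seeds, and
internal Monte-Carlo constants use fixed internal seeds, so identical
calls give bit-identical results and pipeline reruns produce
byte-identical artifacts. The test suite checks parameter recovery on
simulated cohorts of 5,000 subjects (moment properties on up to 50,000,
where a 3% band is several Monte-Carlo standard errors wide), oracle
equivalence of SampEn and the divergence rate against brute-force
implementations on 1,000-sample epochs, and the full analysis chain on a
20-subject synthetic cohort; these sizes keep the suite comfortably
under a few minutes on one CPU while leaving the statistical checks
well-powered.

## Known limitations

* The composite's published weighting is not bundled; without external
  weights the composite is an equal-weight cohort-standardized score.
* Realignment assumes upright, predominantly straight-line walking with
  a stable orientation within an episode.
* The ws/error split relies on day-level data and Gaussian day noise;
  with a single value per week the split is declared unavailable rather
  than guessed.
* Sample-size results apply to a paired pre/post comparison of one
  characteristic; multiplicity across characteristics, dropout, and
  parallel-group designs are out of scope.
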