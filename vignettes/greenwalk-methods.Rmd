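---
title: "Methods: continuous HRV and cortisol analysis for crossover walk studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuous HRV and cortisol analysis for crossover walk studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenwalk)
```

## The design being analysed

greenwalk analyses a within-subject crossover: each participant walks two
routes — a nature ("green") route and an urban control — on different days,
in randomised order. A session is a seated ~5 min pre-rest, a walk of
roughly 20 min (the urban walk is paced to exactly 20 min, the green walk
runs 20–22 min), and a seated ~5 min post-rest, recorded continuously as
inter-beat (NN) intervals by a chest ECG device. Salivary cortisol is
sampled before and after each walk; mood (POMS vigor and total mood
disturbance) and state mindfulness (MAAS) are scored before and after.

The scientific questions the pipeline answers are: (1) does walking the
green route raise heart rate variability (HRV) relative to the urban route
within a subject, and for whom; (2) how does salivary cortisol fall across
each walk, and does the crossover order modulate it; (3) how do during-walk
HRV levels relate to post-walk mood once pre-walk mood and baseline HRV are
controlled for.

## From beats to windowed HRV

Recordings are ingested as plain delimited text (one interval in ms per
row, with phase annotations per beat or in a sidecar file). Cleaning uses
two standard time-domain artifact rules, both configurable:
physiological bounds of 300–2000 ms, and a successive-relative-difference
filter that drops a beat differing from the previously retained beat by
more than 20%. The retained beats keep their *original* cumulative clock so
that window boundaries are unaffected by deletions. The source data for
this kind of device contain occasional corrupted stretches; a recording
losing more than 20% of its beats is flagged unusable and its subject is
excluded (and logged) rather than aborting the cohort. The cleaning rule is
sequential, hence idempotent: cleaning a cleaned series removes nothing.

Phases are half-open `[start, end)` intervals on the cumulative clock, and
a beat belongs to the phase containing its end time; the single exception
is the recording's final boundary, which is inclusive, so that slicing the
three phases partitions the retained beats exactly. This convention is
deterministic and duration-preserving; the alternative (closing every
right edge) would double-count boundary beats.

Three time-domain metrics are computed: RMSSD (root mean square of
successive differences, parasympathetically dominated), SDNN (sample
standard deviation, `n - 1` denominator — the convention is fixed here so
that tests are deterministic), and AVNN (mean interval). During a walk they
are computed over consecutive non-overlapping 60 s windows aligned to the
walk start (alignment to the recording start would shift windows by the
pre-rest length; walk-start alignment makes windows comparable across
sessions). A 20-min walk yields 20 windows. A final partial window is kept
only if it holds at least 10 beats; a full window with fewer than 10 beats
(possible after heavy cleaning) is emitted with missing metrics rather than
imputed — the spline stage below bridges it. Baselines use the whole rest
phase unwindowed, requiring at least 60 s.

## Trajectory resampling

Because walks differ in length (20 vs up to 22 min) and windows can drop
out, the windowed series of the two arms cannot be paired directly. Each
walk's windowed metric is therefore fitted with a cubic smoothing spline on
window midpoints over normalised time `[0, 1]` and resampled at 20 equally
spaced points. Midpoints (not window starts) are used as abscissae because
they are unbiased for a linear trend within a window. The 20-point
trajectories are what the paired tests consume; per-subject summary tables
use the raw window means, not the spline points.

The smoothing factor `s` deserves care because no universal scale exists
across spline libraries. Here `s` is a normalised penalty weight on
`[0, 1)` mapped to the classical penalised-least-squares parameter by
`lambda = s / (1 - s)` on the normalised time axis: `s = 0` is the exact
natural interpolating spline (fit MSE 0), the fit MSE is non-decreasing in
`s`, and `s -> 1` collapses onto the least-squares line. `lambda` is not
additionally rescaled by the data's variance: both the residual sum of
squares and the curvature penalty already scale with the square of the
response, so a fixed `lambda` keeps the fit equivariant under rescaling of
the metric. Internally `lambda` is capped at `1e4`, where the fit already
agrees with the least-squares line to about `1e-5` ms and the penalised
system is still well conditioned. The default `s = 0.4` corresponds to a
heavily smoothed trend; replicating any other library's smoothing scale
bit-for-bit is explicitly not claimed, and one global `s` is applied to
all subjects rather than per-subject tuning. Negative spline excursions
(possible near sparse data) are clamped to 0 ms and flagged.

## Stratification and group summaries

Subjects are stratified by the signs of their green-minus-urban changes in
mean walk RMSSD and SDNN (means over the raw 60 s windows): both positive
gives group 1 (higher HRV in nature — reduced physiological stress), both
negative group 2, mixed signs group 3. An exact zero on either metric is
treated as inconclusive (group 3); with continuous data this is a
measure-zero choice, fixed for determinism. The paired test per subject and
metric is a two-sided paired t-test on the 20 position-matched trajectory
points, coded `**` for p < 0.01 and `*` for p < 0.1, boundaries belonging
to the weaker code.

Group summaries report, per HRV metric, the mean and sample sd of the
per-subject deltas, and *two* relative-change conventions that genuinely
differ:

* `pct_delta_*`: the ratio of group-level arm means,
  `(mu_green - mu_urban) * 100 / mu_urban`;
* `mean_subject_pct_*`: the mean of per-subject percent changes
  `delta / urban * 100`.

For cortisol, the group change is the mean per-subject difference in
percent change, and the relative column applies the ratio-of-means formula
to per-arm *magnitudes of decrease* (so a deeper green-arm decline prints
as a positive relative change, matching the reporting convention of the
summary tables this package reproduces). `group_aggregate()` additionally
offers `hrv_subset = "significant"`, restricting the HRV aggregates to
subjects whose paired test reached a code on at least one metric (falling
back to the whole group when none did). Regression tests against the
embedded published per-subject table show this combination — significant
subset plus per-subject percent convention — is the one that reproduces
the published group-level HRV row for the strong-responder group; the
package computes both so users can choose explicitly. Reported sd always
uses the `n - 1` sample convention, uniformly.

The order analysis is deliberately simple, mirroring the stratified-means
reporting of crossover attenuation: the mean cortisol percent change of
each subject's second-day walk, split by which condition came second. No
crossover ANOVA or mixed model is fitted, and no multiple-testing
correction is applied anywhere — raw p-values are exposed and the partial
correlations are reported as a descriptive pattern.

Partial correlations between post-walk scale scores and HRV adjust for the
pre-walk scale score and the same-day baseline (pre-rest) value of the same
HRV metric. They are computed by residualising both variables on the
covariates plus intercept and correlating the residuals — algebraically
identical to the recursive partial-correlation formula, which the tests
use as an independent oracle, and transparent about the implied linear
model. Inputs with `n < k + 3`, collinear covariates, or residual variance
at round-off level raise errors rather than returning fragile numbers.

## Cortisol calibration

Quantitation follows standard bioanalytical practice: a 9-point 2x serial
dilution from 50 ng/mL (bottoming out at ~0.195 ng/mL), a through-origin
weighted least-squares line with `1/x^2` weights relating response to
concentration, and back-calculation `(response / slope) * dilution_factor`
with a default 5x sample dilution. With `1/x^2` weights the through-origin
slope is exactly the mean of the per-standard response ratios `y/x`, which
the tests exploit as a closed-form oracle. Responses are treated as
internal-standard-normalised peak-area ratios; the mathematics is identical
for raw areas. Since R-squared for through-origin fits is
convention-dependent, both a weighted and an unweighted version (each
`1 - RSS/TSS` about the respective mean) are reported. Samples outside the
calibrated range are flagged, not silently extrapolated.

## The synthetic cohort generator

No public recording archive exists for this kind of study, so the
generator is a first-class module: it emulates the statistical structure
the analysis assumes, with stored ground truth, so every stage is testable.

NN series are a constant mean plus a slow sinusoid (period 100 s, carrying
long-range variability), a fast sinusoid (period 4 s, a respiratory sinus
arrhythmia analogue carrying beat-to-beat variability) and white noise.
On the nominal beat grid the stationary expectations are closed-form:

$$\mathrm{SDNN}^2 = \tfrac{a^2}{2} + \tfrac{b^2}{2} + c^2, \qquad
\mathrm{RMSSD}^2 = 2a^2\sin^2(\pi\Delta/P_s) + 2b^2\sin^2(\pi\Delta/P_f) + 2c^2,$$

with amplitudes `a`, `b`, noise sd `c` and mean beat interval `Delta`.
Given target SDNN and RMSSD the amplitudes are solved from these
identities (`c` is a small fixed device-noise floor), and infeasible target
pairs raise an error naming the violated bound. This model was chosen over
an integral-pulse-frequency-modulation simulator because the closed forms
make targets exactly solvable and the tests sharp; physiological realism
beyond second-order statistics is not needed to exercise the analysis.

Defaults encode the study conditions: 850 ms mean interval; baseline RMSSD
40 ms and SDNN 65 ms (typical urban-day seated baselines for such
cohorts); 17 subjects split 9/6/2 across groups; green-walk multipliers
x2.0 RMSSD / x1.5 SDNN for group 1 and x0.6 / x0.7 for group 2, matching
roughly-doubling and one-third-drop responder patterns. Group 3 uses x1.05
RMSSD / x0.95 SDNN: a mixed response must tilt the two metrics in opposite
directions to be a systematic (rather than purely accidental) phenotype,
and these values sharpen the observed near-zero mixed pattern just enough
to be resolvable from a single 20-min recording. Cortisol starts log-normal
(median 6 ng/mL) and drops by a mean fraction 0.53 (green) / 0.37 (urban)
with between-session sd 0.12; the crossover order interaction adds
`+0.125` to the second-day drop when green is second and `-0.125` when
urban is second — a centred interaction, so marginal arm means stay at the
configured drops under a balanced order. Post-walk vigor couples positively
(and mood disturbance negatively) to the during-walk RMSSD target, on top
of the pre-walk score. Artifacts are injected as beat-detection failures —
splits (false detection) and merges (missed beat) — which preserve the
cumulative clock, as real detector errors do, while being removable by the
cleaning filters.

What the generator does *not* emulate: circadian cortisol drift,
respiration-locked nonstationarity, movement artifacts correlated in time,
scale floor/ceiling effects in mood scores, or any real participant's
record. Passing recovery tests therefore demonstrates that the pipeline's
inference is correct under its own assumptions — not that those
assumptions hold for any particular device or population.

## Problem sizes and numerical conventions in the test suite

The suite (about 500 assertions) runs in a few seconds: estimator
properties use 10,000-beat i.i.d. series; generator faithfulness is checked
at 5, 10 and 20 minutes; end-to-end tests use a 3-subject cohort with
shortened (2 min rest / 10 min walk) sessions, and the full parameter
recovery uses the default 17-subject cohort at full session length, which
is the study-scale configuration. Report tables round half away from zero
(integers for percent summaries, one decimal elsewhere); JSON output is
unrounded. All randomness flows from a single configured seed, and a given
configuration and seed reproduce a cohort byte-identically.

## Known limitations

* The spline smoothing scale is implementation-defined (documented above);
  only its limits and monotonicity are portable claims.
* Paired t-tests on 20 smoothed trajectory points inherit the smoothing's
  variance reduction; their p-values are comparative descriptors within
  this pipeline, not calibrated error rates for raw physiology.
* The stratification is a sign rule on two noisy deltas; subjects with
  near-zero true effects are classified essentially at chance, which is
  why recovery guarantees are stated for the cohort, not per subject.
* Frequency-domain and nonlinear HRV indices, ECG R-peak detection, and
  vendor device formats are out of scope.
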