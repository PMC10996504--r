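---
title: "Methods: analysis of cross-modal conditioning sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysis of cross-modal conditioning sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalattn)
```

## The experimental design this package analyzes

A head-fixed, water-restricted mouse is presented with two stimuli: a 2-s
air puff to the distal whiskers (tactile) and a 2-s drifting grating on a
monitor (visual). One modality — the CS+ — is followed by a water reward
at stimulus offset; the other (CS-) never is. Training starts with a
*shaping* task (one stimulus per trial, balanced 50:50, onset-to-onset
gaps Uniform(8, 12) s) and advances to the *full* task, in which the two
modality streams run independently so that neither stimulus predicts the
timing of the other or, for the CS-, of reward.

The package provides (i) generators for both schedules with a verifiable
flat-hazard property, (ii) a ground-truth synthetic session simulator
(spikes, licking, pupil, whisking), and (iii) the full analysis chain:
lick-index learning metrics, signal conditioning, unit QC, response
classification and selectivity, latency, offset-period statistics, the
anatomical-position model, and movement-regression correction.

## Stimulus scheduling and the hazard rate

Full-task inter-stimulus intervals are drawn per modality as

$$\mathrm{ISI} = \mathrm{Exponential}(\text{mean } 10\,\mathrm{s}) +
\mathrm{Uniform}(8, 12)\,\mathrm{s},$$

clipped at 55 s and rounded to the nearest whole second, giving a mean
ISI of 20 s (the cap introduces a downward bias of roughly 0.1 s).
Rounding (rather than flooring) was chosen for the "binned by seconds"
step and is recorded in the run configuration; the 55-s cap clips rather
than redraws. Beyond the 12-s offset support the hazard of this
distribution is exactly flat: the probability of the next stimulus
falling in a 1-s bin, given it has not yet occurred, is
$1 - e^{-1/10} \approx 0.095$ for every bin. `hazard_rate()` estimates
this per bin as (# intervals ending in the bin) / (# intervals at risk),
reporting bins without survivors as `NA` rather than zero. The shaping
schedule, by contrast, has a hazard rising as $1/(12 - t)$ across
[8, 12) s — the timing is predictable, which is exactly why the full task
exists.

Shaping schedules use a random permutation of an exactly balanced label
vector rather than i.i.d. coin flips, so the two modalities have equal
counts in every session. Session length is the last stimulus offset plus
a 5-s margin. Each generator uses a single seeded RNG and records the
seed in the schedule metadata; identical seeds reproduce schedules
bit for bit.

## The lick index

For each presentation,
$$\mathrm{LI} = \frac{n_\text{stim} - n_\text{base}}{n_\text{stim} + n_\text{base}},$$
where $n_\text{base}$ counts licks in the 2 s before onset and
$n_\text{stim}$ licks during the 2-s stimulus; licks within ±50 ms of
onset are ambiguous and excluded from both windows. Presentations with
no licks in either window are *undefined* and excluded from session
means (not imputed as zero) — with sparse baseline licking an imputed
zero would bias session means toward "ignoring". If a stimulus duration
other than 2 s is ever used, counts are rate-normalized first; the
record flags this extension. Advance-to-full requires the session's CS+
LIs to be significantly above zero (one-sided Wilcoxon signed-rank,
minimum three shaping days); training is complete when CS- LIs are not
significantly different from zero (two-sided, minimum four full-task
days).

## Signal conditioning

**Pupil.** Radius is the geometric mean of the fitted ellipse's
semi-axes. Cleaning excludes samples deviating from a 3-s running median
by more than 25% of that median (blink artifacts), linearly interpolates
them, then smooths with a 5-frame moving average; a trace with more than
50% flagged samples is rejected with a diagnostic. The 25% threshold is
a free parameter (the exclusion rule's magnitude is not standardized);
artifact removal precedes smoothing so a blink is not smeared before it
is detected. The smoothing span is 5 frames at the native frame rate.

**Whisking.** The mean whisker angle is band-pass filtered 4–30 Hz with
a zero-phase 4th-order Butterworth (forward–backward; only the band
itself is prescribed, the filter family is our choice). The analytic
signal's phase defines the whisk cycle; envelope anchors are taken from
the *unfiltered* angle at phase-0 (protracted) and ±π (retracted)
samples, linearly interpolated between anchors and held constant beyond
the first/last anchor. Whisking amplitude is the upper minus the lower
envelope, floored at zero (interpolation between noisy anchors can
otherwise cross). All streams can be aligned to a common 1-kHz timeline
by linear interpolation, with event times rounded to the millisecond.

## Unit quality control

Units with more than 10% of inter-spike intervals below 3 ms are treated
as multi-unit contamination and excluded; exactly 10% passes (strict
"> 10%" reading). Region assignment uses a synthetic atlas of
axis-aligned boxes at paper-scale stereotaxic coordinates for POm, LP
and VPM; units within 50 µm of their region's boundary are labeled
`border` and excluded from region analyses. Spontaneous rate is the
spike count over *quiet epochs* — maximal intervals at least 6 s long
that contain no lick, stimulus (counted for its full 2-s duration), or
reward and start at least 2 s after the last such event — divided by
their total duration, and is undefined when no epoch qualifies.
Consumption licks count as events for this rule (conservative).

## Response classification and selectivity

Presentations are first filtered for cross-modal overlap: a stimulus
with any other-modality onset within 6 s (onset-to-onset, inclusive,
symmetric — both members of a close pair drop) is excluded. Per retained
presentation, spikes are counted in a baseline window
$(t_0 - 1, t_0 - 0.05]$, a stimulus window $(t_0 + 0.05, t_0 + 1]$
(the ±50-ms band around onset is ambiguous), and an offset window
$(t_\text{off}, t_\text{off} + 2]$.

Per unit, a one-way ANOVA compares three groups — all baseline rates
(both modalities pooled), air-puff stimulus rates, grating stimulus
rates; this pooled three-group form is used because one omnibus test per
unit is corrected, not one per stimulus. ANOVA p-values are
Holm–Bonferroni corrected within each cohort × region family at
α = 0.05. For corrected-significant units, paired Wilcoxon signed-rank
tests of stimulus vs same-presentation baseline rates (per modality,
uncorrected, α = 0.05) assign the label `puff` / `grating` / `both` /
`none`. The "paired ranked-sum" phrasing is internally contradictory;
the paired signed-rank test is used, matching the signed-rank tests used
everywhere else in this design. Units with degenerate variance are
marked untestable.

For significant units the selectivity index is
$$\mathrm{SI} = \frac{|FR_A - FR_B| - |FR_V - FR_B|}
{|FR_A - FR_B| + |FR_V - FR_B|} \in [-1, +1],$$
undefined (explicit `NA`, never 0) when both deviations vanish. SI is
antisymmetric under exchanging the two stimulus rates and invariant to
common positive rescaling; both properties are tested.

**Latency.** Firing is binned at 10 ms and trial-averaged; baseline mean
and SD come from the 1-s pre-onset bins. Latency is the left edge of the
first bin starting a run of ≥ 2 consecutive bins beyond 2.576 baseline
SDs (two-sided — increases and decreases both count; 2.576 is used
verbatim rather than recomputing the quantile). Units with no qualifying
run starting within 500 ms return none. A zero baseline SD is floored at
a small epsilon and logged.

**Position model.** SI is regressed on
`DV + ML + AP + CT + CT:DV + CT:ML + CT:AP` (CT = conditioning-type
factor), requiring ≥ 20 units with defined SI, both cohorts, and a
full-rank design. Per-term p-values, the model F-test p and adjusted R²
are reported.

**Offset period.** Per unit and modality, baseline-subtracted rate
changes for the stimulus and offset periods enter within-cohort paired
signed-rank tests (puff vs grating) and a conditioning-type × stimulus-type
two-way ANOVA. The unrewarded stimulus uses the same 2-s post-offset
window as the rewarded one.

## Movement regression

Firing rate, lick rate, whisking amplitude and pupil radius are binned
on one 250-ms grid (bin sizes 50–500 ms give qualitatively similar
results in this design; 250 ms balances spike counts against behavioral
timing). Each unit's rate is fit by OLS on the three movement predictors
plus an intercept — the intercept *is* the baseline term, so the
residuals are a baseline-subtracted, movement-corrected rate. Predictors
are standardized internally for conditioning and coefficients reported
on the original scale; constant predictors are dropped with a message.
Pupil enters the regression simultaneously (unlagged); lagged
relationships are examined separately by the cross-correlation, defined
at lag $\ell$ as $\mathrm{cor}(r_t, x_{t-\ell})$ so that a positive lag
means activity follows the movement variable. The regression is fit on
whole-session bins (the trial-restricted alternative is noted in the
configuration as `fit_scope`).

## The synthetic-data generator

The generator's role is to realize the statistical structure the
analyses assume, with recorded ground truth. Spikes are inhomogeneous
Poisson generated by Lewis–Shedler thinning against a piecewise-constant
1-ms rate function
$$r(t) = b \cdot g(t) + c_p z[\mathrm{pupil}(t - 1\,\mathrm{s})] +
c_w z[\mathrm{amp}(t)] + c_l z[\mathrm{lick}(t)],$$
floored at zero with a logged warning. $g(t)$ multiplies in the modality
gain from onset + latency for the response duration and the offset gain
for 2 s after CS+ offset; couplings apply to z-scored signals (units:
Hz per SD) with pupil lagged 1 s by default, reflecting where
firing–pupil cross-correlations peak. Because the rate function is
exactly piecewise-constant, the time-rescaling theorem gives an exact
test: integrating $r$ over simulated spike times must yield unit-mean
exponential intervals, which the suite checks by KS test across seeds.

Defaults define the study conditions and are not tuned per run: 2-s
stimuli, rewards at CS+ offset, baselines 2–20 Hz with POm skewed above
LP, gains 1.5–4, latencies 20–150 ms, response durations 0.8–1.8 s,
offset gains 1.5–3 in 60% of units. In the visual cohort the tactile
gain increases with ML position at 2 gain-units/mm around the POm ML
midline, creating the laterally clustered touch-selective subregion the
position model is meant to recover. Coupling weights are drawn as
0–8% of baseline per signal SD — proportional modulation keeps rates
positive and matches the modest movement R² regime the regression
operates in.

Behavior: licking is inhomogeneous Poisson — 0.2 Hz tonic baseline
(sparse, as for water-restricted mice outside reward; this sparseness is
also what makes quiet epochs for the spontaneous-rate rule exist at
all), 4 Hz anticipatory rate during the CS+ in non-naive states, 7 Hz
consumption for 2 s after reward, and suppression during the puff for
non-naive visual-cohort animals on correlated shaping schedules
(learned "withholding"). Lick-rate magnitudes are free parameters, not
literature values. Pupil is a slow AR(1) drift plus alpha-function
kernels: dilation to the puff, transient constriction at grating onset,
dilation at reward, and an extra grating dilation in trained
visual-cohort animals. Whisker angle is an 8-Hz carrier (slowly
wandering frequency) whose peak-to-trough amplitude is the ground-truth
amplitude signal: a constant base plus *spontaneous* AR(1) fluctuations
plus a puff-evoked kernel. The spontaneous component matters: without
stimulus-independent whisking variance, the movement predictors would be
collinear with the stimulus and the regression could absorb genuine
sensory gain, destroying the coupling/gain dissociation the residual
analysis exists to demonstrate.

What the generator does *not* emulate: biophysical spiking (no
refractoriness by default — an optional dead-time parameter exists to
exercise the QC filter), bursting, adaptation, correlated noise across
units, video artifacts beyond impulsive pupil dropouts, or
learning-rate dynamics across sessions. Passing recovery tests
therefore demonstrate correctness of the estimators under the assumed
model, not robustness to every property of real recordings.

## Validation strategy and problem sizes

The package validates itself by parameter recovery and error control on
synthetic data (`run_recovery_suite()`): schedule statistics from 10⁵
ISIs; latency recovery on 50 units × 100 trials (median absolute error
≤ 10 ms, one bin); family-wise error on 200 null units (fraction
corrected-significant ≤ 0.05); the movement-correction dissociation on
50 coupling-only vs 50 gain-injected units (paired sign test, p < 0.01);
position-model recovery over 100 simulated populations of 300 units
(interaction sign recovered in ≥ 90%; under a zero slope the rejection
count over 100 seeds is itself a Binomial(100, 0.05) draw, so the suite
checks consistency with the nominal 5% level by exact binomial test
rather than a literal ≤ 5 count, which a correct implementation would
fail ~38% of the time). These sizes keep each check's Monte-Carlo error
well inside its acceptance margin; `reduced = TRUE` runs smaller
versions with the same thresholds for quick iteration.

## Numerical and degenerate-input choices

* Window membership is half-open `(a, b]` throughout; spike times are
  continuous so boundaries have measure zero.
* The latency detector floors a zero baseline SD at 1e-9 (logged);
  all-zero paired differences yield p = 1 rather than an error.
* Overlap exclusion is onset-to-onset and inclusive at 6 s.
* Envelope interpolation beyond the first/last anchor is constant;
  amplitude is floored at 0.
* `hazard_rate()` never zero-fills bins without survivors.
* Rank-deficient position designs and single-cohort inputs are rejected
  with diagnostics rather than silently refit.
* Every output table carries an MD5 hash of the full run configuration,
  and re-running with the same (config, seed) reproduces tables byte
  for byte.

## Known limitations

* The synthetic atlas is axis-aligned boxes; border distances in real
  atlas geometry are not planar.
* The movement regression is OLS with three simultaneous predictors; no
  regularization, spike-history terms, or per-animal random effects
  (cells are pooled, as in the design this implements).
* With strongly stimulus-locked movement and little spontaneous
  movement variance, movement regression can absorb genuine sensory
  responses; the dissociation guarantee holds in the simulated regime,
  not universally.
* The lick detector is a threshold-crossing device with a fixed
  debounce; electrical lick-sensor artifacts are out of scope.
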