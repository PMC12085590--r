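---
title: "Methods: trial-based analysis of social versus object touch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based analysis of social versus object touch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented by
`socialtouch`, the defaults and their units, the numerical edge-case
policies, and the design choices made where the procedure was genuinely
open. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The assay and its timeline

A motorized platform presents a stimulus — a stranger mouse (social
context) or an object (object context) — to a head-fixed mouse in repeated
bouts: 5 s of touch while the platform is stopped, then a 5 s
interstimulus interval (ISI) during which the platform withdraws by 1 cm.
At the platform speed of 1.65 cm/s the out-and-back travel takes
`2 * 1 / 1.65` ≈ 1.2 s of the ISI. A 30-minute session therefore holds
exactly 180 presentation bouts; the two-day voluntary/forced protocol uses
40 bouts per context and choice condition. Trial time 0 is always the
platform stop. The platform trace models the withdrawal as a triangular
excursion with slopes of ± the platform speed placed at the start of the
ISI, so the time spent off the touch position per ISI equals the travel
time; a physical stage would dwell at the withdrawn position, but only the
on/off-touch timing matters to any downstream window.

## Spike processing

Spike trains are binned at 50 ms (half-open bins `[t, t + 0.05)`, an
edge spike counts in the later bin, so `sum(rate) * width` conserves the
spike count), smoothed with a 250 ms centered moving average (window
shrinks at the series edges; no padding, so constants are preserved),
aligned to platform stops over [−2, +7] s (2 s before touch onset to 2 s
after touch end; trials extending past the recording are dropped and
reported), and z-scored to the ISI baseline. The baseline mean and SD are
pooled over all pre-touch ISI bins across the aligned trials — the
z-scoring is per unit and condition, not per trial. A constant baseline
(SD = 0) is replaced by a floor of 0.1 and the unit flagged rather than
dropped.

Unit curation keeps units with ISI-violation fraction < 0.10, amplitude
cutoff < 0.10, and median amplitude > 50 µV (all strict; missing metrics
reject with reason `"missing"`). Regular-spiking units are those with
waveform peak-to-trough ≥ 400 µs, inclusive. Region assignment uses
config-supplied half-open depth intervals `[min, max)` ordered dorsal to
ventral (vS1, tSTR, BLA); depths at a shared boundary belong to the deeper
region, and depths outside all intervals are `"unassigned"`. The package
deliberately does not infer regions from electrophysiological landmarks —
that requires probe-track histology outside this scope.

## Response clustering

Clustering is run per choice condition (voluntary, forced), pooling
contexts and genotypes: the z-scored trial-averaged PSTHs form a
time × unit matrix, PCA keeps the smallest component count explaining
> 95 % of variance, and k-means is run over many random restarts
(10,000 by default; the validation suites use 100, which the stability
matrices show is already saturated on separated data). The reported
assignment is the restart with the lowest within-cluster sum of squares;
the co-assignment matrix (fraction of restarts in which two units share a
cluster) is the stability evidence. K is chosen by the gap statistic
against a uniform reference over the bounding box of the scores (B = 50
draws), taking the smallest k with `Gap(k) >= Gap(k+1) - SE(k+1)`. Cluster
labels are canonicalized by descending mean stimulus-window z of the
centroid, since raw k-means labels are arbitrary. Clusters are merged into
response classes by the centroid's mean z over the 5 s stimulus window:
excited above +0.25, suppressed below −0.25, weak otherwise; the threshold
is exposed because the merge in the source procedure involved visual
inspection that software should make explicit.

## Modulation indices

The modulation index `MI = (FR_stim − FR_ISI) / (FR_stim + FR_ISI)` is
bounded in [−1, 1], antisymmetric in its arguments, and invariant to
common rescaling; both rates zero yields NA. Three window variants (in
seconds relative to the platform stop): STIM compares [0, 5] against the
5 s ISI of the same bout cycle — the source is silent on whether the
preceding or following ISI was used, so the following ISI [5, 10] is the
default with `isi_side = "preceding"` available; SHORTSTIM compares [0, 3]
against [−3, 0]; PLATFORM compares [−1, 1] against [−3, −1]. Per-unit MI is
the index of trial-averaged window rates (the formula is stated on mean
rates), not the mean of per-trial indices; the aversion split recomputes
the trial average separately over aversive-flagged and unflagged
presentations. For a Poisson unit with multiplicative stimulus gain g, the
expected MI converges to `(g − 1)/(g + 1)` as trials grow — the test suite
checks this at 200 trials. Variant selection per cluster
(`select_mi_variant`) keys off the centroid: an onset transient selects
PLATFORM, sustained change selects STIM, both select SHORTSTIM; the
thresholds are configurable because the underlying rule was qualitative.

## Preference classification

Each trial's presentation-period rate t_i (mean over [0, 5] s) is turned
into a decision variable using leave-one-out context means: for a social
trial `DV = t_i * (mean(other social) − mean(object))`, for an object trial
`DV = t_i * (mean(social) − mean(other object))`. The multiplicative form
is implemented literally. One consequence deserves emphasis: both context
DV sets are scaled by a mean difference of the same sign, so exchanging the
social and object trial sets flips every DV's sign rather than exchanging
the two distributions — the auROC-complement identity holds at the ROC
integrator (`roc_auc(b, a) == 1 − roc_auc(a, b)`) but not through the DV
construction, and equivalence with the Mann–Whitney statistic holds exactly
on instances where all leave-one-out mean differences are positive. An
alternative reading of the notation (function application rather than
product) exists but is not the default.

The auROC sweeps the criterion over all DV values and integrates
trapezoidally; ties contribute half credit, so identical distributions give
exactly 0.5 (this exactness requires the tied DVs to be bitwise equal,
which holds whenever the trial rates are identical binary-representable
numbers). Significance uses a label-permutation null: context labels are
re-dealt across trials without replacement (a with-replacement variant is
selectable), the DV → auROC pipeline is recomputed per draw (1000 by
default), and the two-sided p-value is `(r + 1)/(n + 1)` counting draws at
least as far from 0.5 as observed. Excited units with significant
auROC > 0.5 are social-preferring and < 0.5 object-preferring; for
suppressed units the mapping reverses; non-significant units are `"none"`.

## Population decoding

The context decoder is a soft-margin kernel classifier with a
radial-basis-function kernel and box constraint 1 — fixed hyperparameters,
no tuning — with 10-fold cross-validation on the training split. Each of
100 iterations draws a random unit subsample (1–20 units for the
size-sweep, 10 for time-resolved decoding) and a stratified 80/20
train/test split; reported accuracy is the iteration mean ± SE. The source
description of the test split ("20 %, 26/80") is internally inconsistent —
26/80 is 32.5 % — so the fraction 0.20 (16 of 80) is the default.
Stratification is applied on both sides of the split. Time-resolved
decoding fits an independent classifier per 50 ms bin across [−1, +2] s.

Controls: shuffling the held-out trial labels; shuffling context labels of
a configurable fraction (default 80 %) of presentations before splitting;
and permuting each neural feature column independently across trials while
behavioral columns stay aligned — the last is the "neural activity shuffled
in time" control isolating whether locomotion alone can decode. Units whose
second-session baseline departs from the first session's mean by strictly
more than 1.5 SD of the first session's per-trial baselines are excluded
from decoding; single-trial baselines leave the SD undefined, and such
units are kept and flagged. Behavioral decoders use either all 23 face-label
motion energies or the aversive set (running avoidance, eye area, saccade
direction, whisker protraction), trial-binned at 100 ms.

## Linear encoding model

For forced-touch sessions a 13 × 80 design matrix is built, one column per
presentation, with regressors ordered: context (social = 1), running
avoidance (binary), orbital (eye) area, whisker protraction (binary),
whisker / eye / pupil / mouth / nose motion energies, pupil size, running
motion energy, signed saccade count, locomotion (binary). Each regressor is
its trial mean over the 5 s presentation. Continuous regressors are
standardized across trials; binaries stay {0, 1}; a constant continuous
regressor is zeroed and flagged rather than dropped, keeping the matrix
shape stable. Pupil appears twice by design — once as motion energy and
once as size — because both were distinct variables in the source
regressor list.

The fit is ridge regression solved in closed form on centered data (the
intercept is unpenalized), with the penalty chosen by k-fold (default 5)
cross-validated squared error over a logarithmic grid spanning
`10^-3 … 10^3` times the mean diagonal of the centered Gram matrix. At
λ → 0 on a full-rank design the solution equals ordinary least squares to
machine precision, which the suite checks at 10⁻⁶. `cvR² = 1 − SS_cv /
SS_tot` may be negative; a negative session-level cvR² excludes the animal
from group summaries (per-unit flags are also emitted, since the exclusion
rule was stated at the animal level). β weights are normalized by the sum
of absolute weights — the normalization must be sign-preserving with a
positive denominator, because a plain sum of signed weights can vanish or
flip sign while the reported weights are signed. Group summaries keep the
10 non-binary regressors plus context.

## Synthetic sessions and what they do and do not show

The generator plants ground truth at the study's conditions: 40 bouts per
context × choice block (5 s stimulus / 5 s ISI), Poisson units in three
depth-assigned regions drawn from four temporal archetypes — transient
excited (Gaussian bump peaking ~0.4 s after the stop), sustained excited
(3× gain across the stimulus), suppressed (0.25×), unmodulated — with a
context-dependent multiplicative gain applied during the stimulus window
only, so a planted gain g yields the closed-form MI expectation. Spikes are
drawn per 1 ms sub-bin with uniform jitter. Behavior is emitted at 120
frames/s by default (tests use 30–60 to keep fixtures small): 23 face
labels with Gaussian pixel noise over slow common facial motion, ball
motion energy with a signed direction channel, and per-bout aversive
epochs (probability 0.6 for object, 0.2 for social touch by default —
object touch is the aversive context) that couple backward running,
orbital tightening (40 % eye-area contraction), forward whisker
displacement, and a temporal saccade. Archetype allocation is
deterministic (largest remainder), and spikes and behavior draw from
independent sub-streams of one seed so either can be regenerated alone.

Behavior–firing coupling, when enabled, is log-linear
(`rate ∝ exp(Σ β·regressor)`) so rates stay positive; the encoding model is
linear, so recovery tests use small couplings where the exponential is
near-linear. The generator does not emulate: spike-sorting artifacts or
drift, inter-unit noise correlations beyond shared behavior, realistic
whisker mechanics or video, or genotype differences — passing
ground-truth-recovery tests therefore demonstrates correctness of the
estimators under the stated model, not robustness to every property of
real recordings.

## Problem sizes and numerical policies

The validation suites run at deliberately modest sizes chosen to keep the
checks sharp: 100 k-means restarts (the co-assignment matrix is already
degenerate at 1.0/0.0 on separated data), 40-unit populations for
clustering recovery, 80-trial sessions for decoder calibration and power,
200 permutation draws for the preference-null calibration (the function
default remains 1000), and 200 trials for the MI convergence check.
Degenerate-input policies are uniform: empty or constant inputs flag and
return NA rather than erroring where a value is expected downstream
(zero-SD baselines, all-zero β, both-zero MI rates), and error early with
the offending name where analysis cannot proceed (missing files, dangling
unit ids, unknown labels, inconsistent PSTH windows).
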