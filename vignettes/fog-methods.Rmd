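---
title: "Step-level detection and prediction of freezing of gait: methods"
author: "fogpredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step-level detection and prediction of freezing of gait: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fogpredict)
```

## The problem

Freezing of gait (FOG) is an episodic inability to progress the feet that
affects a large fraction of people with advanced Parkinson's disease.
Episodes are heterogeneous — trembling legs at roughly 4–7 Hz, shuffling,
or complete akinesia — and are preceded, in the few seconds before onset,
by a measurable degradation of the walking pattern: swing amplitude and
velocity decrease, steps become faster and shorter, and the stride's
spectral content shifts toward higher frequencies. `fogpredict`
implements a step-level analysis of the shank angular-velocity signal
(the x-axis gyroscope channel, `omega_x`, sampled at 60 Hz from one
device per shin) that (a) detects steps, (b) describes each step with 16
time- and frequency-domain features, and (c) trains cost-sensitive
classifiers to separate normal gait from FOG (detection) and from the
pre-FOG interval (prediction), the latter enabling pre-emptive cueing.

## Signal conditioning and step segmentation

Each leg's trace is first mean–range normalized,
`x' = (x - mean(x)) / (max(x) - min(x))`, giving a zero-mean, unit-range
signal; the map is affine, so all subsequent relative thresholds become
subject-independent. Normalization statistics are computed once per trial
and per leg over the full trace (the alternative — computing them after
removing the sitting prefix — is a one-line change in `normalize_signal`
callers; we document the full-trace choice because the prefix is part of
the recorded range on real devices too).

The two devices start recording at slightly different times. Both record
the same high-amplitude sit-to-stand transient, so the traces are aligned
by superimposing the stand-up peaks: each peak is located as the maximum
absolute amplitude within the first 10 s, the index difference is the
inter-device delay, and the later trace is trimmed accordingly
(`synchronize_legs`). Peak-index difference is used rather than
cross-correlation because the anchor event is a single unambiguous
transient; on noise-free synthetic data the alignment error is below one
sample period. Samples up to the stand-up time plus a 3.5 s settling
interval are flagged non-gait and excluded from step detection.

Mid-swing peaks anchor the segmentation: local maxima at least 350 ms
apart whose height reaches 20% of the maximum peak height of the same leg
and trial. The separation rule is enforced greedily by descending height
(ties keep the earlier peak), which is deterministic and discards
duplicate detections. "Maximum value" is interpreted per leg and per
trial because the two legs are processed separately throughout. Peaks
inside annotated FOG episodes are retained — they become the FOG class of
the detection task. Akinetic episodes produce no supra-threshold peaks
and therefore no steps; such intervals simply contribute no rows.

Two slices are cut per retained peak: *Type I*, from the previous
same-leg peak (exclusive) to the current peak (inclusive), so consecutive
Type I slices tile the trace; and *Type II*, the positive lobe containing
the peak, found by walking outward to the nearest non-positive samples.

## The 16 step features

Time domain: standard deviation, range and RMS of the Type I slice;
angular jerk `0.5 * integral(omega_ddot^2 dt)` and its time-normalized
variant on the Type II slice (second derivative by central differences
scaled by the squared sample rate, trapezoid integration); dynamic time
warping (DTW) cost between the current and previous same-leg Type I
slices (absolute-difference local cost, symmetric step pattern, no
window; 0 for identical strides); step time (current peak to previous
contralateral peak) and stride time (to previous same-leg peak); and the
height and half-power width (`height / sqrt(2)` threshold, interpolated
crossings) of the Type II lobe.

Frequency domain, all on the mean-removed Type I slice zero-padded to a
512-point FFT with a rectangular window: power spectral entropy
`-sum(P * log(P + 0.001))` with natural logarithm (the stabilizing
constant keeps empty bins finite; the log base is a documented constant —
any base rescales the feature monotonically and is absorbed by the
classifiers); the principal (non-DC) harmonic's frequency, amplitude and
half-power width (`amplitude / 2` threshold, since the spectrum is
already a power quantity, versus `1/sqrt(2)` for the time-domain
amplitude width); the weighted power spectral peak (amplitude x
frequency); and the low power frequency, the fraction of spectral power
at or below 2 Hz. Zero-padding is chosen because Type I slices are only
~60 samples long and padding stabilizes the arg-max interpolation; DC is
excluded from the harmonic search (mean removal makes it ~0 anyway).

Two readings in the source material are ambiguous and resolved as
follows: step time is listed as a Type II feature but defined from peak
timing, and peak times are the only computable reading, so it is computed
from peak times; "weighted power spectral peak" and "weighted power
spectral frequency" are treated as the same amplitude-x-frequency
quantity. Normalized jerk divides by the slice duration (the literal
reading); the dimensionless-jerk alternative is not used.

Steps lacking a previous same-leg stride or a previous contralateral peak
(the first one or two steps of each leg per trial), and degenerate
segments whose positive lobe is shorter than three samples (possible
inside trembling episodes), are dropped rather than imputed; this
discards only boundary steps and guarantees a feature matrix with no
undefined values.

## Labels

A step is FOG iff its mid-swing peak time lies inside an annotated
episode; pre-FOG iff it lies within the pre-FOG window before an onset
and inside no episode (so a window that reaches back into a preceding
episode is truncated at that episode's end — a step inside FOG cannot be
pre-FOG); gait otherwise. Membership is decided by the peak instant, not
by slice overlap, so every step has exactly one unambiguous label. The
detection task codes FOG = 1 against everything else (would-be pre-FOG
steps count as gait; the alternative of excluding them is supported via
the window parameter but off by default). The prediction task drops FOG
steps, codes pre-FOG = 1, and — mirroring the clinical exclusion — first
removes episodes flagged as occurring at gait initiation, where no
walking precedes the episode. The window length is swept over 2–5 s
during model selection and fixed at 2 s for the final configuration.

## Classifiers and validation protocols

Feature relevance is ranked with the fixed decision tree (Gini split,
minimum leaf size 1, at most 15 splits): features splitting closer to the
root rank higher; ties break by total Gini impurity decrease, then by
column order, and unused features are appended in column order, making
the ranking deterministic and always complete.

The classifier zoo and hyperparameter ranges: SVM (linear / quadratic /
gaussian kernel, kernel scale 0.001–100, box constraint 0.01–100), kNN
(1–50 neighbours, euclidean or manhattan metric, equal / inverse /
squared-inverse vote weights), regularized LDA (pooled covariance shrunk
toward its diagonal by `gamma` in 0.01–1, discriminant coefficients with
magnitude below `delta` in 0.01–100 zeroed) and ridge logistic regression
(`lambda` in 0.01–100). The false-negative cost is implemented as the
standard cost-sensitive mechanism of each family (SVM class weights,
LDA prior multiplier, observation weights, vote weights, tree loss
matrix); a nominal cost of 0 is treated as 1, since a zero FN cost would
never predict the positive class.

Four protocols are provided. (1) Stratified 10-fold CV. (2) The repeated
70/30 procedure: twenty independent stratified splits; per split, the
tree ranking and an exhaustive inner grid over the feature count (1 to
16) and SVM cost (1 to 20), each cell scored by inner stratified 10-fold
CV, are computed on the training 70% only; ties prefer fewer features,
then smaller cost. (3) Leave-one-subject-out (LOSO): one fold per
subject, with ranking, tuning and fitting repeated inside each fold on
the remaining subjects only; per-fold selected-feature lists feed a
selection-frequency table, and features selected in at least 80% of folds
are correlated (Spearman, average ranks, large-sample p-value) with the
class label. Inside LOSO only the feature count is tuned, over a coarse
grid at 5-fold inner CV with the supplied model spec: the full 16 x 20
grid at 10-fold inner CV in every LOSO fold would multiply the cost of
the protocol roughly fifty-fold without changing what the fold tests
(subject generalization), and the source procedure prescribes the full
grid only for the 70/30 protocol. (4) Cross-condition transfer: the full
pipeline runs on one therapy condition's rows and is evaluated on the
other's.

Window length and model family are selected jointly: for each
window-family pair, a seeded random search with a 30-evaluation budget
over the ranges above. Each sampled configuration is first screened with
a cheap 2-fold CV and only the six best screened configurations receive
the full stratified 10-fold evaluation — the analogue of an optimizer's
acquisition pruning — so the reported cell accuracy is always full
10-fold CV. A random search of fixed budget is used as the seeded,
deterministic stand-in for a Bayesian optimizer of equal budget; with 30
draws per cell the best-of-budget accuracy is stable to within a point
across seeds on the synthetic cohorts. FN-cost tuning sweeps costs 1–10
with shared CV folds and picks the cost maximizing sensitivity subject to
the F-score staying within 5 points of its unweighted value. The
SVM+LDA OR-ensemble classifies a step positive if either model does;
inside LOSO both members are refit jointly per fold.

All protocols are pure functions of (data, configuration, seed): every
stochastic stage draws from a seed derived deterministically from the
master seed, and each protocol records per-fold row provenance (train,
test, ranking and tuning row indices) so leakage is assertable.

Performance is summarized by sensitivity, specificity, accuracy, PPV,
NPV, F-score and the Youden index, all in percent, with zero-denominator
metrics flagged `NA` rather than forced to 0 or 100 (small LOSO folds can
lack a class); ROC curves sweep the unique score values and AUC uses the
trapezoid rule, which equals the normalized Mann–Whitney statistic on
tie-free scores. Detection latency counts, per episode, the consecutive
steps immediately before onset predicted pre-FOG (the strictest reading
of "recognized N steps before onset"); a looser first-hit-in-window
variant is available behind a flag. Episodes with no pre-onset steps are
excluded from the aggregate and counted in a coverage report.

## The synthetic cohort

Patient recordings are not distributable, so the package ships a
generator that emulates exactly the statistical structure the analysis
relies on. One trial is: quiet sitting; a single biphasic sit-to-stand
transient with amplitude twice the maximum swing amplitude (shared
trial-clock event, per-device random start offset of 0.1–0.7 s, so
synchronization is a non-trivial recovery problem); a 3.5 s settle; then
alternating-leg walking in which each swing is a raised-cosine positive
lobe (default duration 0.45 s, a swing phase of ~45% of the stride
cycle) with a smaller negative inter-swing trough. Per-subject parameters
are drawn once per cohort: cadence 0.85–1.15 strides/s per leg, swing
amplitude 0.8–1.2 (arbitrary units; normalization removes scale), noise
SD 0.03–0.07.

Within a configurable window before each episode onset (default 2 s),
degradation ramps linearly from none to its onset depth: swing amplitude
multiplied down to `amp_decay` (default 0.5), step period down to
`steptime_shrink` (default 0.7), and a 6 Hz component with amplitude up
to `freq_shift` (default 0.25) of the swing amplitude added — the three
signatures of pre-FOG gait. A linear ramp is the minimal assumption and
makes the window-length accuracy trend testable: labels beyond the true
degradation window are statistically gait. Episodes are trembling
(sinusoid at 4–7 Hz, amplitude 0.3 of the swing amplitude, cosine-tapered
edges) with probability 0.85, otherwise akinetic (noise only). Off-
therapy trials scale the degradation depth by 1.5 (deeper amplitude/step
shortening, stronger frequency shift), emulating the attenuating effect
of dopaminergic therapy on pre-FOG degradation in on-therapy trials.
With probability 0.2 a trial carries an extra flagged episode at gait
initiation. These effect sizes are free parameters of the generator, not
claims about Parkinson's physiology: the source cohort's effect sizes
are unpublished, so the defaults are chosen once as values a movement
analyst would call a clearly present but noisy signature, and the
acceptance thresholds are read against those fixed defaults.

The default cohort is 10 subjects x 2 trials (one per condition) of 60 s
at 60 Hz with 3 episodes per trial — roughly 2 000 analyzable steps,
~15% of them pre-FOG at the 2 s window. That size keeps every protocol
(including LOSO with per-fold tuning and the budget-30 random searches)
in the minutes range on a single core and still leaves each LOSO fold
with both classes.

What the generator deliberately does *not* model: multi-axis signals,
turning and sit-down phases, stride-length asymmetry between legs,
sensor drift, and FOG phenotype mixtures within an episode. Passing
tests therefore demonstrate that the pipeline recovers planted structure
of the kind the analysis assumes — not clinical performance on patient
data. Because in this generator the degradation simultaneously moves
amplitude, timing and spectral content, *all* 16 features carry some
class signal, with the amplitude decay (halved swing height at onset) a
markedly stronger plant than the step-time shrink or the frequency
shift; the planted-recovery checks therefore assert that the amplitude
features sit in the frequently-selected set and that the timing features
carry the right correlation sign, rather than that the selected set is
small (sparsity is checked separately on constructed feature matrices
with exactly three informative columns).

## Numerical choices and degenerate inputs

Normalization rejects constant traces explicitly. Peak detection treats
plateaus as their first sample. Half-power widths interpolate crossings
linearly and clip at slice boundaries. The spectrum normalizes to unit
sum and rejects all-zero slices. DTW uses a rolling two-row dynamic
program. LDA falls back to a pseudo-inverse when the shrunken covariance
is singular. Tie-breaks are always toward the smaller model (fewer
features, then smaller cost), and argmax ties in model selection prefer
the shorter window. Undefined performance metrics propagate as flagged
`NA`. All RNG flows through a per-call seeded generator; no function
touches global RNG state.

## Known limitations

The LOSO inner loop tunes only the feature count (see above). The
latency aggregate uses all covered episodes whether or not any pre-FOG
step was detected, which is the conservative reading. The generator's
on/off effect is a single multiplicative knob; interactions between
therapy state and cadence or noise are not modeled. Bayesian
hyperparameter optimization is represented by an equal-budget seeded
random search.
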