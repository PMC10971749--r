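---
title: "Methods: temporal-feature EEG depression screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal-feature EEG depression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depscreen)
```

## Scope and model

`depscreen` implements a screening pipeline for major depressive disorder
from resting-state EEG recorded with three dry pre-frontal electrodes
(Fp1, Fpz, Fp2). The underlying premise is that group differences between
depressed and healthy subjects are expressed in simple temporal-domain
statistics of the cleaned signal — amplitudes, moments, roughness and
histogram entropy — so the pipeline is deliberately time-domain only: no
band decomposition, no spectral, wavelet or nonlinear features.

Labels are binary with *depressed = 1* as the positive class throughout;
all metric conventions (precision, recall, ROC) follow from that choice.

## Preprocessing

The cleaning order is fixed: average reference, notch, smoothing,
windowing.

* **Average reference.** Each channel gets the per-sample mean across
  channels subtracted, so the output channels sum to zero at every
  sample. With only three frontal electrodes this mainly removes
  common-mode contamination — the 50 Hz powerline pickup and most of each
  blink, both of which are nearly identical across closely spaced
  forehead electrodes.
* **Notch (50 Hz, Q = 30).** A second-order IIR notch (Audio-EQ-Cookbook
  biquad: zeros on the unit circle at the notch frequency, pole radius
  set by the quality factor), applied forward and backward for zero phase.
  Each pass starts from the steady state of a constant input equal to its
  first sample and the ends are extended by a 9-sample odd reflection, so
  a constant signal is reproduced exactly and edge transients stay in the
  discarded pads. Contracts verified in the tests: a pure 50 Hz tone is
  attenuated by more than 20 dB, a 10 Hz tone by less than 1 dB, and DC
  passes to machine precision. 50 Hz is the regional mains frequency of
  the data the protocol was designed around; it is configurable.
* **Smoothing.** "Third-order smoothing" is read as a centred
  moving average of window 3, the common reading in EEG cleaning; a
  running-median alternative of the same window is available via the
  `smoothing` config tag since the filter family is a design choice, not
  a given. Edges shrink the window symmetrically, making constants fixed
  points and preserving length.
* **Windowing.** The first `chunk_seconds` (default 40 s, offset
  configurable and defaulting to 0 since nothing pins down *which* 40 s a
  9-s-longer recording should contribute) are cut into
  `chunk_seconds / window_seconds` contiguous non-overlapping windows
  (default 10 s). Sample indices are 0-based and intervals half-open, so
  the windows partition the chunk exactly; 55 subjects × 4 windows = 220
  instances.

## The feature bank

Twelve statistics per electrode per window, always in this column order:
`max_amp`, `min_amp`, `mean`, `std`, `kurtosis`, `skewness`, `p2p_value`,
`p2p_time`, `mad1`, `mad2`, `energy`, `entropy`. Conventions that matter:

* Moments use the population (1/N) form; kurtosis is non-excess
  (Gaussian ≈ 3). Zero-variance windows make kurtosis and skewness
  undefined: the functions raise an error which `extract_features()`
  surfaces with the subject/window identity rather than letting silent
  `NaN`s reach the selection correlations.
* `p2p_time` is signed (time of global maximum minus time of global
  minimum, seconds); extrema ties resolve to the first occurrence.
* `energy` is mean power, (1/N)Σs². A literal transcription of the
  formula as sometimes printed (without the square) would duplicate the
  mean; the prose definition — signal energy in the interval — is the
  standard squared form, which is what is implemented.
* `entropy` is Shannon entropy −Σ p log₂ p over a 16-bin equal-width
  amplitude histogram spanning the window's own [min, max] (the
  conventional negative sign is used so that more irregular windows score
  higher; a constant window is 0 by convention). Bin count 16 is a free
  parameter: source material specifies no binning, and 16 bins on
  2500-sample windows keeps occupancy high while still resolving shape.

Every statistic is checked against an independently coded brute-force
oracle on hundreds of random windows at 1e−9 relative tolerance, plus
shift/scale equivariance properties.

## Feature selection

CFS scores a subset S of k features with Hall's merit
M(S) = k·r̄_cf / √(k + k(k−1)·r̄_ff), where r̄_cf is the mean absolute
point-biserial correlation with the label and r̄_ff the mean absolute
pairwise Pearson correlation inside S. Merit rises with class relevance
and falls with redundancy; duplicating a feature can never beat the
singleton. Correlations are computed on the raw continuous features
(Weka's variant discretizes and uses symmetric uncertainty; raw
correlations were chosen as the default because nothing mandates the
discretized form and they keep the merit analytic).

The search is best-first forward search from the empty set: the open
subset with the highest merit is expanded by every single-feature
addition, and the search stops after 5 consecutive expansions that fail
to improve the best merit (the conventional stale limit). Ties break
towards the lower feature index, making selection deterministic. On
random problems with up to 10 features the search returns exactly the
exhaustive-enumeration optimum in all tested trials.

Three fusion strategies wrap the search:

* **Majority rule** (the pipeline default): search each electrode's 12
  columns separately; keep features selected on ≥ `quorum` electrodes
  (default 2 of 3, parameterized for other montages); the final columns
  are all (electrode, common feature) pairs, so the feature-vector length
  is a multiple of the electrode count. An empty common set is an
  explicit error, not a silent fallback.
* **Early fusion**: one joint search over all 36 columns.
* **Late fusion**: concatenation of the per-electrode subsets with their
  electrode tags.

In plain 10-fold evaluation, selection defaults to being computed once on
the full matrix (`selection_scope = "global"`), mirroring the workflow in
which selection is treated as feature definition; `"per_fold"` recomputes
it on each training fold and is the recommended leak-free protocol. The
nested-CV mode always refits selection inside its inner folds.

## Classifiers

All three are implemented in the package behind one train/predict
contract, with fixed documented tie-breaks so reimplementations can be
compared bit-for-bit: distance ties → lower training-row index; stump
ties → lower column, then lower threshold; leaf majority ties → class 0.

* **kNN** (k = 3): Euclidean distance on min-max-normalized features,
  bounds learned on the training fold (constant columns map to 0). An
  even vote falls to the nearest neighbour's label.
* **AdaBoost.M1** over one-split decision stumps, 10 rounds,
  reweighting; learner weight ½·ln((1−ε)/ε); a perfect stump is kept with
  a capped weight and stops the boosting, a stump at or above chance
  stops before being added; sample weights are renormalized every round.
* **Best-first tree**: binary splits at midpoints of distinct sorted
  values; node impurity is Gini; the frontier leaf with the largest
  count-weighted impurity decrease is expanded next, to purity or the
  `min_leaf = 2` floor. Pruning runs an internal 5-fold CV over the
  number of expansions E. Because the minimum of a CV curve over many
  candidate sizes is biased low on uninformative data, the rule is
  conservative: the root is kept unless the best size beats it by more
  than two cross-fold standard deviations of the error, otherwise the
  smallest size within one such spread of the minimum wins, and the tree
  is regrown on all data stopped at E*. This keeps pure-noise labels at
  the root in ≈97/100 seeded trials while always expanding on cleanly
  separated fixtures.

## Evaluation

Stratified k-fold assignment keeps fold sizes within one instance and
class counts within one per fold; a rotating per-class pointer makes both
guarantees hold simultaneously. With `group_by_subject = TRUE` whole
subjects are assigned to folds (stratified by subject label). The default
instance-level CV mirrors the 220-window protocol, but note the caveat:
with 4 windows per subject, windows of one subject can land in both
training and test folds, which optimistically biases instance-level
results; the grouped mode is the defensible protocol and is reported
alongside in the package's own analyses.

Metrics come from the pooled confusion matrix over all held-out folds:
accuracy (percent), per-class precision/recall/F combined by
support-weighted averaging (the "weighted avg" convention), and Cohen's
kappa (p_o − p_e)/(1 − p_e) with the degenerate p_e = 1 case defined as
0. ROC curves sweep every unique score as a threshold and integrate by
trapezoid; scores are vote fractions (kNN), normalized ensemble margins
(AdaBoost) and leaf class fractions (tree). AUC is checked against an
independent implementation and is invariant to monotone score
transforms.

Nested CV uses outer 10 / inner 5 stratified folds; the inner loop picks
the selection strategy (none / early / late / majority) by pooled inner
accuracy, ties going to fewer final columns and then to the earlier
candidate. The structure of what the inner loop tunes is a design choice
of this package; outer test rows are never touched by the inner loop.

Per-feature Welch t-tests (unequal variances, Welch–Satterthwaite df)
compare depressed vs healthy instances per column; raw p-values are
reported with Benjamini–Hochberg q-values alongside, and per-group
quartiles plus kernel-density points are attached so violin plots can be
drawn from the report alone.

## The synthetic cohort generator

The generator exists so that every downstream stage has a realistic,
fully reproducible input without clinical data. Each subject's channel is

pink (1/f) noise (20 µV sd) + an alpha oscillation (10 µV, subject-specific
frequency in 8–12 Hz) + blink transients (300 ms raised-cosine pulses,
~200 µV, 12/min, near-common-mode across the three forehead channels with
±10 % gain spread) + a common-mode 50 Hz powerline tone (5 µV),

scaled by a subject-level log-normal amplitude effect (sd 0.1). Group
effects for the depressed class are a multiplicative amplitude reduction,
additive white-noise roughness (raising the first/second-difference
features), and an optional DC offset. Broadband temporal statistics do
not need precise spectral realism, which is why a pink + alpha base
suffices. One cohort seed derives per-subject child seeds, so any subset
of subjects regenerates identically; the whole cohort is bit-reproducible
under its seed.

`generate_separable_cohort(margin)` maps a separation margin to effect
sizes (amplitude effect 0.22·margin capped at 0.8, roughness
0.06·margin). The coefficients were calibrated once against the pooled
window-level standard deviations of the four majority features under the
default cohort settings so that `margin = 3` yields at least a 3-sd class
separation in each of them on every electrode; `margin = 0` reduces
exactly to zero-effect generation.

What the generator does **not** emulate: real spectral shape beyond 1/f +
alpha, topographic structure, ocular/muscle artifacts other than the
stylized blink, non-stationarity, medication or comorbidity effects, and
— most importantly — any actual electrophysiology of depression. The
effect directions are fixtures. Consequently, passing pipeline tests on
synthetic cohorts demonstrates that the machinery recovers a planted,
learnable signal and stays at chance when there is none; it says nothing
about accuracy on clinical recordings.

## Statistical calibration choices

Two subtleties are deliberate:

* **Type-I calibration uses one window per subject.** Even at zero group
  effects, a subject's four windows share latent draws (alpha frequency,
  slow 1/f components), so window-level t-tests on 220 correlated
  instances are anti-conservative (~8–9 % rejection at nominal 5 % in
  this generator). The calibration suite therefore generates cohorts with
  a single 10-s window per subject and zero subject-level spread, under
  which the measured rejection rate is within three binomial standard
  errors of 5 % over ~1000 replicate columns. The window-level inflation
  is the same phenomenon as the subject-leakage caveat in CV.
* **Permutation control.** On the separable cohort with permuted labels,
  pooled 10-fold kappa stays within ±0.15 of zero, confirming the
  pipeline cannot manufacture signal from bookkeeping.

## Problem sizes and numerics

The test and demonstration cohorts use the default 55 subjects; full-rate
(250 Hz, 90 s) cohorts are used for the headline pipeline runs, and
reduced-rate cohorts (125 Hz, 10–40 s) for replicated statistical checks
— sizes chosen to make the planted effects measurable with comfortable
statistical margins while keeping a complete run in seconds. Double
precision throughout; merit and gain comparisons use 1e−12 slack so
floating-point noise cannot flip deterministic tie-breaks; the EDF writer
quantizes to the 16-bit range spanning each channel's extrema and the
reader restores microvolts from the header scaling, so a round-trip is
exact to one quantization step.

## Known limitations

* The EDF reader targets continuous single-rate EDF; EDF+ annotations,
  discontinuous records and BDF are out of scope.
* Instance-level CV is the default to mirror the 220-instance protocol
  despite its leakage caveat; grouped CV is one flag away.
* The merit's point-biserial correlation treats the binary label
  linearly; the discretized symmetric-uncertainty CFS variant is not
  implemented, only the raw-correlation form.
* Classifier hyperparameters (k, rounds, pruning constants) follow the
  cited tool-chain conventions rather than per-dataset tuning; the nested
  CV tunes only the selection strategy.
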