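---
title: "Principal-mode models of squat and lunge joint kinetics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal-mode models of squat and lunge joint kinetics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kineticsm)
```

This vignette is the package's account of its statistical method: the model,
its assumptions, the preprocessing and validation machinery, the numerical
choices, and the design decisions that were genuinely open. The companion
README shows a worked example; here we explain *why* things are done the way
they are.

## The data and its preprocessing

A trial is a raw recording of one squat or lunge repetition: a knee-flexion
channel (degrees) and six joint-reaction-force channels — hip and knee, each
in three fixed perpendicular planes — in body-weight units (BW). Trials from
different subjects differ in duration, sampling phase and the amount of
quiet standing captured before and after the movement, so they must be
aligned before any cross-subject statistics make sense.

Alignment follows three rules:

1. **Peak pinning.** The frame with peak knee flexion defines 50% motion
   progress. Ties are broken to the earliest frame, which is deterministic
   and stable under reordering. A constant flexion trace, or a peak at the
   first or last frame, makes a trial unusable (there is no descent/ascent
   to align) and raises an error rather than producing a silently distorted
   curve.
2. **Trimming.** Leading and trailing standing posture is irrelevant
   transient. No universally agreed threshold exists, so we trim to the
   maximal contiguous window around the peak in which knee flexion stays at
   or above `min + trim_frac * range`, with `trim_frac = 0.05` by default
   and configurable. Five percent of the flexion range cuts quiet standing
   (a few degrees) without touching the movement itself; `trim_frac = 0`
   disables trimming, which is also what makes re-alignment of an
   already-aligned trial an exact no-op.
3. **Resampling.** 51 evenly spaced samples span window start to peak
   (0–50% progress) and 50 more span peak to window end (51–100%), by
   linear interpolation. Linear interpolation cannot overshoot on sharp
   force transients, which higher-order schemes can; the value at instant
   51 is copied from the peak frame exactly, not interpolated.

For the lunge, only the closed-chain phase (forward foot on its force
plate) is modelled: open-chain execution is too arbitrary between subjects
and mostly adds noise. Trials carry an explicit closed-chain flag; when a
vertical ground-reaction channel is available instead,
`derive_closed_chain()` flags a trial closed-chain when that channel stays
above 0.05 BW throughout the motion window — a small threshold safely above
sensor noise and safely below any real foot contact. Squat trials always
pass.

When a subject performed the motion several times, the aligned 6×101
matrices of retained trials are averaged into one column. Averaging is the
simplest estimator of the subject's typical execution and keeps one column
per subject, which the inter-*subject* model requires; no published
convention exists for collapsing repetitions, and alternatives (median,
best trial) would change little for smooth waveforms.

Feature vectors stack the six channels in a fixed order (HJRFx, HJRFy,
HJRFz, KJRFx, KJRFy, KJRFz), each contributing its 101 instants in progress
order, for 606 observations. This ordering is a contract: element 304 is
always KJRFx at 0% progress.

## The model

With `p` subjects the training matrix `X` is 606 × p. Each observation row
is mean-centered and divided by its standard deviation (denominator p−1) —
the *correlation-matrix* convention. Forces in different planes differ by
an order of magnitude; without row standardization the decomposition would
be dominated by the largest-amplitude channels rather than by correlation
structure.

The standardized residual matrix is decomposed by thin SVD, `R = U L Aᵀ`:
`U` holds orthonormal waveform-space modes, `A` orthonormal subject-space
loadings, and the eigenvalues are `λ_k = l_k²/(p−1)`. Two consequences fix
the scaling conventions:

* Because every one of the 606 rows has unit variance, the eigenvalues sum
  to exactly 606. Compactness (cumulative variance) is therefore
  `Σ_{m≤k} λ_m / Σ λ`, and the per-mode "percent of variance" is
  `100 λ_k / 606`. This is the only scaling under which a printed spectrum,
  its percentage column and its cumulative column are mutually consistent.
* Truncated reconstruction is `x̂ = x̄ + D Σ_{m≤t} z_m u_m` with no extra
  `1/p` factor: at full rank this returns every training column exactly
  (to machine precision), which is the identity any reconstruction formula
  must satisfy.

Subjects are treated as samples and the 606 observations as variables:
modes are waveform-shaped curves and a subject's score on mode k is
`l_k A_ik`, with variance `λ_k` across subjects. Mode signs are fixed so
the largest-magnitude element of each mode is positive — sign is arbitrary
in any SVD, and a deterministic convention makes serialized models
reproducible bit for bit.

Components with `λ < 10⁻¹⁰ λ₁` are dropped at fit time; they are numerical
zeros (the centering alone guarantees one) and keeping them would make
"full rank" operations ill-conditioned. Models serialize to a single JSON
file at full double precision; a write/read round trip preserves metadata
exactly and numerics to better than 1e−12.

## Validation

Four estimators quantify model goodness, all reporting RMSE in BW after
un-standardization (errors in standardized units would be uninterpretable
clinically):

* **Accuracy** (`model_accuracy`): in-sample reconstruction error at `t`
  modes. The error is computed per subject *and* per channel (RMSE over the
  101 instants) and summarized as median ± IQR. A grand mean over subjects
  of the full-vector RMSE is also exposed; the median/IQR convention is
  preferred because per-channel error distributions are skewed.
* **Compactness**: the cumulative variance curve, plus
  `n_components_for_variance()` giving the dimensionality at a variance
  level (smallest k reaching the level).
* **Generalization** (`generalization_curve`): for each training-set size
  `n`, repeatedly hold out one uniformly chosen subject, fit on `n`
  subjects sampled without replacement from the rest, keep the number of
  modes reaching 95% variance, and reconstruct the held-out subject. This
  mixes leave-one-out with random subsetting deliberately: cycling the
  held-out subject exhaustively while also enumerating subsets is
  combinatorially infeasible, and uniform sampling of both gives an
  unbiased picture of out-of-sample error as a function of sample size —
  a post-hoc sample-size analysis.
* **Specificity** (`model_specificity`): sample virtual subjects, find each
  one's most similar training sample, and summarize those nearest-sample
  RMSEs. Nearest matching is done in BW space — virtual subjects are
  intended to be used in BW space, so their plausibility should be judged
  there. By default virtual subjects draw standard-normal scores on *every*
  retained mode (`sampling = "full"`); the variance level then only labels
  the run, and specificity is nearly level-independent — differences
  between levels are pure Monte-Carlo jitter. This matches how the
  virtual-subject formula is defined (the sum runs over all modes) and is
  the only reading under which reported specificity values at different
  levels can agree to three decimals while truncated sampling would force
  them apart by several percent (expected squared distance grows like
  `1 + compactness(t)`). `sampling = "truncated"` is available for the
  alternative reading.

Virtual subjects are sampled as `x̄ + D Σ n_m √λ_m u_m` with independent
`n_m ~ N(0,1)` — a multivariate-normal assumption on mode scores that is
convenient rather than verified, and a known limitation of this model
family.

### Choosing the number of components

`permutation_component_test()` separates signal from noise components with
a Monte-Carlo permutation null: the entries of every observation row are
permuted independently, which preserves each row's marginal distribution
(means, SDs) while destroying the inter-row correlation that principal
components feed on. Each permuted matrix is refitted and its spectrum
compared with the observed one position by position:

* *rank of roots*: is the observed `λ_k` larger than the k-th eigenvalue of
  permuted data? For a genuine signal component the permuted value almost
  never reaches it and the p-value sits at the floor `1/(B+1)`; for a noise
  component the permuted spectrum at that position is typically far
  *larger* (permutation flattens the spectrum, inflating middle
  eigenvalues), so the p-value saturates at 1. The sharp floor-to-1
  transition is what makes the criterion readable.
* *equality of roots*: statistic `λ_k / mean(λ_k…λ_r)` — the k-th root
  against the mean of the remaining roots — detects whether the spectrum
  still has structure beyond position k; it stays significant deeper into
  the tail than rank-of-roots.

A deflation-based variant (remove the first k−1 fitted components, permute
the residual, compare its leading eigenvalue) was implemented and rejected:
on planted-rank cohorts it produces marginal false positives for the first
noise component (the observed residual eigenvalue is "already maximized"
over directions while the permuted one is not, making the test slightly
anti-conservative), and it cannot produce the saturated p = 1 values that
the position-wise comparison yields for noise components. The add-one
correction `(count+1)/(B+1)` keeps p-values valid at finite B; with B = 999
the floor is 0.001.

Every estimator draws from an independently keyed substream of one master
seed, so results are reproducible regardless of call order.

## The synthetic cohort generator

No public squat/lunge JRF cohort exists, so the generator stands in for the
motion-capture + inverse-dynamics front end. It emulates:

* mean force templates shaped as raised-cosine bumps whose hip and knee
  resultants peak at motion-typical magnitudes exactly at 50% progress —
  3.08 / 4.52 BW (hip/knee) for the squat and 4.76 / 7.16 BW for the lunge
  — over a 0.5 BW standing baseline;
* `K` orthonormal planted modes built from a low-order cosine basis (12
  harmonics by default), so modes are waveform-like rather than white.
  Mode amplitude is envelope-modulated toward mid-motion
  (`0.15 + 0.85 sin²`): near standing posture all subjects look alike,
  and inter-subject variability concentrates around peak loading. Without
  this heterogeneity the generator cannot reproduce the characteristic
  validation pattern of real kinetic cohorts, where median in-sample
  accuracy (~0.01 BW) sits an order of magnitude below specificity
  (~0.13–0.16 BW);
* a planted eigenvalue spectrum defaulting to the reference squat spectral
  shape (`reference_spectrum()`), scaled to a total planted variance of
  24 BW², which gives an element-wise inter-subject spread of roughly
  0.2 BW and nearest-neighbour specificity on the 0.13–0.16 BW scale;
* independent Gaussian measurement noise per instant per channel
  (0.01 BW by default — the scale of in-sample accuracy medians);
* raw-recording embedding: standing plateaus of random length (flexion
  ≈ 5°) on both sides and random per-half frame densities, so trimming and
  resampling are genuinely exercised. The raw frame grid always contains
  the integer-progress points, so preprocessing recovers the planted
  aligned curves *exactly*; planted-rank and subspace-recovery tests can
  therefore assert at machine precision rather than against interpolation
  error.

Mode scores are drawn before noise and jitter, so cohorts generated with
the same seed but different noise levels share their planted scores — the
noise-free twin of a noisy cohort defines the "planted" variance fractions
that recovery tests compare against (the fitted eigenvalue estimates the
*realized* sample variance along a planted direction, not the population
value, whose sampling error at p = 100 would be ~14% relative).

What the generator does **not** emulate: biomechanical coupling between
channels beyond the planted covariance, skin-motion or marker artifacts,
force-plate noise spectra, asymmetric or non-smooth execution, and any
kinematic (joint-angle) variability — the flexion template is shared by all
subjects. Passing tests on synthetic cohorts therefore demonstrate that the
estimators and the pipeline are implemented correctly and behave as
designed under known ground truth; they do not certify accuracy numbers on
real motion-lab data.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in well under a minute while every statistical check
retains power: cohorts of p = 50 (squat) and p = 53 (lunge), generalization
with T_g = 200 replicates on a size grid from 4 to p−1, specificity with
T_s = 2000 virtual subjects per level, permutation tests at B = 199
(floor 0.005) and null-calibration at B = 99 over 100 replicate noise
cohorts. The corresponding production-scale parameters (T_g = 10⁴,
T_s = 10⁶, B = 999) are plain function arguments.

Key tolerances: orthonormality and full-rank reconstruction are asserted at
1e−9; eigenvalue conservation (Σλ = 606) at 1e−6 relative; the component
drop threshold is 1e−10 λ₁; serialization round-trips numerics at 1e−12.
Degenerate inputs fail loudly: zero-variance observation rows, constant or
boundary-peaked flexion traces, mixed motions, duplicated subjects and
empty post-filter cohorts all raise descriptive errors.

## Known limitations

* The multivariate-normality assumption on mode scores is untested on real
  cohorts and is known to be optimistic.
* The trimming threshold and trial-averaging rules are defensible
  conventions, not validated against marker-level ground truth.
* Specificity's nearest-neighbour search is O(T_s · p) per level; at
  T_s = 10⁶ it is the dominant cost.
* The model is strictly kinetic: no joint angles are modelled, and the
  analysis assumes forces arrive already body-weight normalized.
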