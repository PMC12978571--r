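---
title: "Models and methods: behavioral-pupillary dynamics under looming threat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: behavioral-pupillary dynamics under looming threat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loomdyn)
```

This vignette is the package's account of its models, the conventions it
adopts where the underlying procedures leave genuine freedom, and what its
passing tests do and do not establish about real data.

## The pipeline at a glance

A looming-threat trial presents a fixation cross (0–300 ms), an expanding
stimulus (300–1,300 ms), then a blank screen during which the participant
imagines the continued approach and presses a key at the judged collision
time. The package analyzes such experiments in six coupled stages:
behavioral screening, psychophysical model fitting, pupil trace
normalization, functional PCA, two-level trial profiling, and Markov-chain
dynamics. A synthetic-data generator produces inputs with exactly the
statistical structure the analysis assumes, which is what makes round-trip
testing possible.

## Stimulus dynamics

Approach velocity is `(screen width − initial width) / aTTC` in px/s. For
the default 1,280-px design with initial sizes of 20% and 30% of screen
width and aTTC ∈ {3, 3.5, 4, 4.5, 5} s, the ten (size × speed) pairs yield
nine distinct velocities from 179.2 to 341.3 px/s — two cells coincide at
exactly 256 px/s (1024/4 = 896/3.5).

Velocities are grouped into five ordinal PSV (physical stimulus velocity)
bins by an equal-width partition of the velocity range. The package takes
the range endpoints at 0.1 px/s precision (the scale at which such
velocities are conventionally reported), giving boundaries 179.2, 211.62,
244.04, 276.46, 308.88, 341.3; binning compares velocities at the same
precision, with left-closed/right-open intervals and a closed last
interval. Exact-endpoint partitions differ from this convention only in the
second decimal.

## Behavioral screening

Trials flagged as technical artifacts are removed first; then, per subject,
trials whose jTTC deviates more than 5 SDs from that subject's mean
(pooled over the subject's remaining trials) are excluded. Two properties
of this pooled rule deserve note: a zero SD excludes nothing, and because
the candidate outlier inflates the pooled SD, the achievable |z| is bounded
by roughly √n, so the rule is deliberately conservative — a single moderate
deviation among tight data is *not* removed unless it is extreme relative
to the pooled spread.

## The psychophysical models

The power law `jTTC = α·aTTC^β` is fitted by minimizing the sum of squared
errors in the response scale. For a fixed exponent the optimal scale has
the closed form `α(β) = Σ(y·x^β)/Σ(x^{2β})`, so the fit is a
one-dimensional profiled search over β: a 101-point coarse grid over
[−1, 4] brackets the basin and two nested calls to Brent's method refine
the minimum to ~1e-9. This is more robust than joint two-parameter descent
(no starting-value sensitivity) and makes scale equivariance exact:
multiplying all responses by c multiplies α̂ by c and leaves β̂ unchanged. A
log-space fit (OLS of log y on log x) is available via `log_space = TRUE`
but is not the default, because the estimand is the least-squares fit in
seconds. The linear baseline is ordinary least squares.

Both models have two mean parameters, and both information criteria use the
profiled-Gaussian convention `n·log(SSE/n) + penalty` with k = 2, so model
comparison reduces to the SSEs; exact ties go to the linear model. Note
that over the 3–5 s range a compressive power curve is close to linear, so
under realistic response noise the power law wins only a modest majority of
per-condition comparisons even when it is the generating model.

Treatment, sex and threat effects on the per-(subject × condition)
parameters are tested with `parameter ~ (arm + sex + threat)^2 +
(1 | subject)` via REML (lme4/lmerTest), placebo/male/non-threat reference
levels, Satterthwaite p-values. Fits with fewer than 10 trials are excluded
from this stage.

## Pupil preprocessing

Traces in camera pixel area are converted to diameter by
`d = α_scale · L · √area` — the square root is the areal-to-linear
conversion, with any remaining proportionality constant folded into the
empirical calibration `α_scale · L`; diameters pass through unchanged.
Cleaning marks zeros/missing samples invalid, pads each invalid run by
100 ms on both sides (blink edges corrupt the signal before the tracker
reports loss), invalidates samples outside a 1.5–9 mm physiological band
(applied only when units are mm) and samples beyond 5 SDs of the trial
mean, then linearly interpolates — never changing the sample count. Trials
with more than 30% interpolated samples are flagged for exclusion; that
threshold is a package convention, chosen as the point at which
interpolation starts to dominate the trace. Down-sampling averages valid
samples into 10-ms bins stamped at the bin start. Baseline correction
subtracts the mean over [0, 300) ms and is idempotent.

Phase summaries use stimulus presentation [300, 1300), early imagination
[1300, 1800), and late imagination [keypress − 500, keypress) ms, with
trials shorter than 2,300 ms excluded so the windows cannot collide.

## Time normalization and smoothing

The piecewise-linear warp maps [300, 1300] ms onto [0, 0.5] and
[1300, keypress] onto [0.5, 1]; it is strictly increasing, bijective, and
exactly invertible, and equal-duration trials share the same warp. Warped
samples are smoothed by a penalized cubic B-spline (mgcv, `bs = "bs"`,
20 basis functions, second-derivative penalty, GCV-chosen smoothing
parameter) and evaluated on a common 101-point grid. The basis size and
grid are package conventions: 20 basis functions resolve features of
roughly 1/20 of a trial, well below the timescale of pupillary responses,
and doubling the grid changes FPCA eigenvalues by under 1%. Samples before
stimulus onset contribute to the baseline only, never to trajectories.
Derivative (velocity) trajectories are finite differences on warped time —
change per unit task progress, not per millisecond.

## Functional PCA

With trapezoid quadrature weights W on the grid, the sample covariance C of
the smoothed, baseline-corrected trajectories defines the generalized
eigenproblem `C W φ = λ φ`, symmetrized as
`W^{1/2} C W^{1/2} v = λ v`, `φ = W^{-1/2} v`. Eigenfunctions are
orthonormal in the quadrature inner product, eigenvalues sum to the total
weighted variance (Parseval), and scores are quadrature inner products of
centered trajectories with each eigenfunction. The covariance surface is
not additionally smoothed — trajectories are pre-smoothed, and a second
smoothing pass would bias the eigenvalues. Signs are fixed by requiring a
non-negative integral over the stimulus epoch [0, 0.5]. Retention takes the
shortest prefix of components whose cumulative share exceeds 85%, then
drops members with individual shares at or below 5% — cumulative rule
first, because applying the individual floor first could never assemble the
intended cumulative coverage from a long tail. FPCA is fitted pooled across
arms by default: cross-arm score comparisons require a common basis;
per-arm fits remain possible by subsetting.

## Two-level profiling

Trials are first split on log jTTC by k-means with k = 2 (the log
transform symmetrizes the multiplicative response noise); the
lower-centroid cluster is E (early), the other L (late). Within each
subgroup, the retained component scores are standardized (scale
comparability across components) and clustered by k-means for k ∈ 2..6,
selecting the k with the best rank-sum of the Calinski–Harabasz index and
mean silhouette, ties to the smaller k. Cluster indices are assigned in
descending size order — the labels are bookkeeping; their interpretation
comes from the per-profile component-score sign table (+/−/~0 with a
|mean z| < 0.2 neutral band).

Two diagnostics are calibrated against reference shapes rather than
nominal guesses, because k-means diagnostics on forced partitions do not
behave as intuition suggests: the mean silhouette of a forced 2-split of
*unimodal* 1-D data is about 0.57 (not near zero), so the level-1 weak-split
flag is 0.65, between that and the >0.8 of well-separated mixtures; and
isotropic multivariate noise yields silhouettes near 0.25, so the level-2
flag is 0.3. Similarly, bootstrap ARI and cross-validated assignment
accuracy for k-means on pure noise are substantially above zero/chance —
Voronoi partitions of an unstructured cloud are partly reproducible — so
stability numbers should be read against those baselines, not against an
assumed zero floor.

Stability is assessed by resampling trials with replacement (default
1,000 replicates), reclustering with the same k, and scoring the adjusted
Rand index against the reference labels on the resampled points; accuracy
by 5-fold cross-validation with nearest-centroid assignment of held-out
trials and exact optimal label matching (enumeration over k!
permutations). Subject-level E/L proportions are correlated (Pearson) with
the fitted α and β, BH-adjusted within the family of four tests; since
proportions sum to one, E- and L-correlations are exactly opposite.

## Markov-chain dynamics

Per-subject profile sequences (trial order) are pooled into an 8×8 count
table using within-subject, within-block consecutive pairs only —
transitions never span subjects or blocks. The transition matrix is the
row-normalized table; unobserved rows are flagged, not imputed. The
stationary distribution is the normalized left eigenvector at eigenvalue 1,
with a multiplicity check (the identity matrix has no unique stationary
law). Occupancy *testing* uses empirical contingency tables (groups ×
states) with Pearson chi-squared and adjusted standardized residuals
`(O−E)/√(E(1−row share)(1−col share))` — the margin-corrected form, since
the |z| > 1.96 criterion presumes unit-variance residuals; the eigenvector
distribution is reported descriptively.

Sequence entropy is the Shannon entropy, in bits, of the empirical
distribution of overlapping length-3 blocks pooled within a group. The
block length is the smallest for which the 7.7–8.1-bit range reported for
eight-state sequences is even reachable (single symbols cap at 3 bits,
trigrams at 9), and it is configurable. The plug-in estimator is biased
downward in small samples (≈ (M−1)/(2N·ln 2) bits for M observed blocks in
N draws), which matters twice: entropy comparisons should use groups of
similar size, and under subject-level bootstrap the percentile interval of
a small group can sit entirely below the point estimate — the reported
intervals are therefore extended to include the estimate, a conservative
widening.

Between-group transition contrasts resample subjects independently within
each group and report per-cell difference CIs (significant = CI excludes
zero) plus bootstrap sign p-values with optional BH correction across the
64 cells; within-group significant transitions use adjusted residuals of
the count table, BH-adjusted across cells, flagging positive deviations.
Attractors are states with self-transition probability above 0.45. BH
families are kept separate by contrast (64 transition cells; occupancy
cells per factor; four proportion correlations; grid points per
coefficient curve).

## Shared statistical machinery

Mixed-design repeated-measures ANOVA aggregates to one cell mean per
subject × within-cell, fits the wide multivariate linear model on the
between-subject design (sum-to-zero contrasts, type-III), and reports the
univariate table with Greenhouse–Geisser epsilon via `car::Anova`;
subjects with incomplete cells are dropped listwise and named. The
functional mixed-model contrast is a deliberate pointwise approximation: at
each grid point, a linear mixed model with the fixed-effect structure and a
subject random intercept, with BH correction across grid points per
coefficient. Higher-order interactions are pruned by likelihood-ratio
tests on the time-averaged response before the pointwise pass (pruning
pointwise would let the model structure vary along the grid). The
approximation cannot represent random slopes in normalized time — a
limitation, not an oversight: the coefficient curves are unsmoothed and
their pointwise CIs ignore cross-grid correlation, so significant *regions*
are interpretable, isolated significant points are not.

## The synthetic generator as study design

The generator's defaults are the study conditions, chosen once:

* **Design.** Three arms (LT, PLC, AVP) × 37 subjects × 160 trials — the
  full 5 × 4 × 2 factorial repeated 4 times, shuffled per subject, split
  into two blocks; snake/spider are threat, butterfly/rabbit non-threat.
  Exemplar identity within a category is treated as a non-modeled label.
* **Behavior.** `jTTC = α_eff·aTTC^β_eff·exp(ε)`, ε ~ N(0, 0.1) on the log
  scale — multiplicative noise keeps responses positive and matches the
  later clustering on log jTTC. Baseline α = 1.5, β = 0.55; additive
  shifts: LT −0.15 on β, AVP +0.30 on α, females −0.167 on β, threat
  −0.09 on β. Effect magnitudes are of the order reported for this
  paradigm; β̂ recovery from 160 noiseless trials is exact to 1e-6.
* **Pupil.** Tonic level 3.5 mm (3.7 mm for AVP); a grand mean response
  `0.3·u(2−u)` mm over normalized time; three orthonormal eigenfunctions
  built by Gram–Schmidt from templates matching the canonical component
  shapes (early rise/plateau; early inhibition/late activation;
  peak–trough–recovery); score SDs in the variance ratio 62:18:7; AR(1)
  noise with coefficient 0.95 and innovation SD 0.056 at 10-ms sampling
  (stationary SD ≈ 0.18 mm of slow drift — fast noise would be absorbed by
  the spline smoothing, and this calibration makes the *measured* FPCA
  shares follow the 62/18/7-plus-noise pattern and retain three
  components); Poisson blinks (1/trial, 100–300 ms gaps). Traces are
  generated directly at the 10-ms analysis rate.
* **Chains.** Each arm's 8×8 transition matrix mixes a self-transition
  weight, pull mass toward attractor profiles, and a uniform remainder:
  placebo 0.38 self + 0.18 toward E1 (E1 self-transition 0.615; analytic
  trigram entropy 7.22 bits), AVP 0.34 self + pulls to E3/L3/L2 (8.01
  bits), LT 0.25 self (8.54 bits) — realizing the qualitative structure of
  an E1-anchored rigid placebo, an intermediate AVP with new stability
  centers, and a maximally flexible LT, with the entropy ordering
  LT > AVP > PLC built into the generating processes themselves.

One seed governs everything, fanned out to fixed per-stage seeds so stages
re-run reproducibly in isolation.

What the generator does *not* emulate: serial dependence between a trial's
behavior/pupil response and the state-sequence module (fitted-profile
sequences therefore show arm effects in occupancy but not in transition
dynamics — only the generator's own sequences carry the configured chains);
gaze position and saccades; calibration drift; non-Gaussian score
distributions; learning or fatigue across blocks. Passing round-trip tests
therefore demonstrates correctness of the estimators under the assumed
generative structure, not robustness to real-data violations of it.

## Problem sizes and numerical choices

The test suite runs its recovery studies at deliberately chosen sizes:
power-law noise recovery at 200 replicates of the 160-trial design; FPCA
recovery at 2,000 trajectories on the 101-point grid; Markov recovery and
bootstrap coverage at the full 37 × 140 per-arm design with 200 outer
replicates and 200 bootstrap resamples; the end-to-end direction check at
50 replicates of the full three-arm design. Chain-estimation sanity checks
use 5 × 10⁴ steps, where a 0.02 max-abs bound is a >3-SE statement (at 10⁴
steps the worst-cell SE is ~0.014, making such a bound a coin flip).
Tolerances follow the same logic throughout: exact identities at 1e-9 to
1e-6, Monte-Carlo assertions at ≥3 SEs of the statistic under test.

Degenerate inputs are errors, not silent results: zero-variance ensembles
in FPCA, identical responses in clustering, non-stochastic matrices,
multiplicity of the stationary eigenvector, empty contingency margins, and
baselines without valid samples all raise with named reasons, and
exclusion paths (short trials, over-interpolated traces, small subgroups,
unobserved chain rows) are flagged and counted rather than dropped
silently.
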