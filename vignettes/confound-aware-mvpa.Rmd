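---
title: "Confound-aware multivoxel pattern classification: model, corrections and scenario design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confound-aware multivoxel pattern classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvpaproj)
```

## The problem

Multivoxel pattern analysis (MVPA) asks whether the *spatial pattern* of
activity across voxels in a region of interest carries information about a
cognitive state — here, which of three associative-retrieval tasks
(spatial, temporal, or pair recognition) a subject is performing on a given
trial. A linear classifier trained on voxel-by-trial response amplitudes
can, however, succeed for reasons that have nothing to do with distributed
patterns:

1. **Mean-amplitude differences.** If one condition evokes uniformly more
   activity across the region, a classifier can read the regional mean and
   ignore the pattern entirely.
2. **Response-time (RT) coupling.** Harder trials take longer and evoke
   larger responses; if conditions differ in difficulty, RT becomes a
   condition-correlated global gain that a classifier can exploit.

The package implements two projection operators that remove these signal
components before training, a per-subject decoding scheme, group-level
permutation inference, and a synthetic-data generator in which each
component can be injected with known ground truth, so the selectivity of
the corrections can be demonstrated as parameter recovery.

## Generative model of the synthetic data

For a subject with $V$ voxels and $T$ trials, the voxel-by-trial amplitude
matrix is

$$D_{vt} = b_v + \mu_{c(t)} + \beta_{\mathrm{pat}}\, w_{c(t),v}
  + \beta_{\mathrm{rt}}\,(r_t - \bar r)\, g_v + \varepsilon_{vt},
  \qquad \varepsilon_{vt} \sim \mathcal N(0, \sigma^2) \text{ i.i.d.}$$

* $b_v$ — per-voxel baseline, drawn once per subject from
  $\mathcal N(100, 10^2)$ (arbitrary units). A non-degenerate baseline
  keeps the voxel-mean direction well-defined and distinct from the
  all-ones direction, which is what makes the mean projection a meaningful
  operation rather than an exact removal of the uniform axis.
* $\mu_c$ — per-condition uniform offset (`mean_effect`), the "mean
  signal" confound.
* $w_c$ — per-condition voxel patterns, drawn once per subject,
  **zero-mean across voxels** and unit norm. Zero-mean by construction, so
  pattern signal contributes nothing to the spatial mean: the pattern and
  mean generators are cleanly dissociated.
* $g$ — the RT loading, fixed to the uniform unit-norm vector
  $g_v = 1/\sqrt V$. RT effects are modeled as a *global gain*, reflecting
  the view of RT-related modulation as regional, not patterned — exactly
  the confound that RT residualization is meant to remove.
* $r_t$ — trial RT in ms, drawn per condition from a normal truncated
  below at 200 ms. Defaults: means 1284 (spatial), 1384 (temporal),
  1183 (pair) ms. The trial-level SD is set to 300 ms for every condition;
  empirical reports of this paradigm give only across-subject standard
  errors of condition means, and 300 ms is a typical trial-level RT spread
  for responses in the 1.2–1.4 s range.
* `incorrect_rate` (default 0.16, the forget rate of the hardest
  condition) flags trials as incorrect; they are generated and then
  excluded downstream, so the correct-trials-only filter is exercised.

The default design is 17 subjects, 80 trials per condition distributed
evenly over 5 runs, $\sigma = 1$. Units are arbitrary throughout — whether
real features are percent signal change or raw GLM betas only rescales the
matrix, and the pipeline standardizes features anyway.

A configuration with all three effect sizes zero is the *null scenario*:
the generator then contains no condition information of any kind.

### Optional timeseries path

`simulate_timeseries()` renders amplitudes into BOLD-like run-wise
timeseries by convolution with the canonical double-gamma hemodynamic
response (peak ≈ 5 s, undershoot ≈ 15 s, unit peak) sampled at TR = 2.5 s,
with jittered inter-trial fixation (0.5–13 s, right-skewed, mean ≈ 4 s).
A fixed canonical response is used as the *forward* model because the
simulator needs a generative kernel; flexible basis sets used for
estimation in empirical work are not generative objects.
`estimate_single_trial_amplitudes()` inverts this with one OLS regressor
per trial plus per-run intercept and linear drift, in a single
concatenated-runs design matrix. In the noiseless case this round trip is
exact to numerical tolerance; rank-deficient designs (e.g. coincident
trials) are rejected with the offending trials named.

## The two projection corrections

Both act on the voxel-by-trial matrix $D$ of correct trials and are
computed within subject across all correct trials (train and test
together). They are label-free, so they cannot leak class information;
whether they should instead be estimated on training data only is exposed
as a choice to the user by applying them manually to any trial subset.

**Mean-signal projection.** Let $m$ be the vector of voxel means across
trials and $\hat m = m / \lVert m \rVert$. Then

$$D' = D - \hat m \hat m^\top D .$$

Every corrected trial column is orthogonal to the region's mean spatial
pattern, so no classifier trained on $D'$ can use signal along that
direction. Normalization of $m$ matters: $\hat m\hat m^\top$ is an
orthogonal projector (idempotent, norm non-increasing) while $m m^\top$
for unnormalized $m$ is not a projection at all and can arbitrarily
amplify the data. If $\lVert m \rVert$ is numerically zero the operator is
the identity (with a warning) — there is no mean pattern to remove. A
useful exact identity: after one application the voxel means are exactly
zero, so re-application takes this degenerate branch and idempotency holds
trivially.

**RT residualization.** Let $\tilde r$ be the mean-centered RT vector.
Each voxel row is replaced by its residual from regression on
$\tilde r$:

$$D' = D - D \tilde r (\tilde r^\top \tilde r)^{-1} \tilde r^\top .$$

This is the residual-maker (annihilator) projector applied on the trial
dimension. Centering $r$ first is essential: raw RTs are strictly
positive, and projecting on the raw vector would also strip most of each
voxel's mean response, conflating this correction with the mean-signal
one. After correction the sample covariance of every voxel with RT is zero
(checked against independent per-voxel `lm()` residuals to 1e-8 in the
tests).

A formula sometimes quoted for the RT correction — $D' = D - PD$ with
$P = E - r(r^\top r)^{-1}r^\top$ — read literally *retains* exactly the
RT-spanned component rather than removing it, the opposite of the stated
goal of controlling for RT. The package implements the intent (remove
RT-explained variance) and keeps the literal operator available as
`rt_correct(..., literal = TRUE)` for comparison. Similarly, a single
left-multiplied correction formula cannot be dimension-consistent for both
corrections under the voxel-by-trial orientation; the mean projector acts
on the voxel dimension (left multiplication) and the RT projector on the
trial dimension (right multiplication), resolved per operator.

## Per-subject decoding scheme

`classify_subject()` decodes one condition against the other two:

1. keep correct trials; label target = +1, others = −1;
2. optionally apply one correction (computed over all correct trials);
3. randomly down-sample the larger class to the smaller class's size;
4. stratified random 80/20 train/test split (both classes equally
   represented in both partitions);
5. tune the SVM regularization constant $C$ by cross-validation within
   the training data, with folds following run boundaries (5 runs give 5
   folds; other run counts are grouped contiguously). The grid is the 11
   decades $10^{-10}, \dots, 10^{0}$ — the stated range with a decade
   spacing adopted here. Ties break toward the smallest (most regularized)
   $C$ for reproducibility;
6. fit the final linear SVM at the chosen $C$ on all training trials and
   report accuracy on the untouched test set.

The classifier is an L2-regularized hinge-loss (L1-loss) linear SVM solved
in the dual by coordinate descent — the LIBLINEAR algorithm — implemented
in compiled code in this package with a regularized bias (augmented
constant feature), convergence tolerance 0.1 on the maximal projected
gradient and a deterministic internally-seeded sweep order, so fits are
bit-reproducible. The test suite cross-checks it against an independent
SVM implementation (libsvm via `e1071`) for prediction agreement and
against direct numerical minimization of its primal objective.

Per-voxel z-scoring is estimated on training rows only and applied
unchanged to test rows (linear SVMs are scale-sensitive; the unscaled
variant is available via `standardize = FALSE`). Down-sampling happens
once per subject per classifier, before splitting. The 80/20 split is
stratified by class and not run-aligned; whether the original scheme
respected run boundaries in the outer split is unknowable from the
description, and the stratified variant keeps class balance exact at every
trial count.

No test-set information reaches any training-side choice: down-sampling
and splitting are label-only operations, standardization and $C$ tuning
see training rows only. On null data the long-run mean held-out accuracy
is 50% (verified at ±2% over 200 subjects in the acceptance tests).

## Group inference

`group_t()` computes the one-sample t of subject accuracies against the
50% chance level. `permutation_test()` builds the group null: per
permutation, every subject's condition labels are shuffled uniformly among
that subject's correct trials (class counts preserved; labels never cross
subjects — between-subject exchange has no meaning here), the per-subject
pipeline is re-run, and the group t recomputed. The one-sided p-value uses
the add-one estimator $p = (1 + \#\{t_b \ge t_{\mathrm{obs}}\}) / (1 + B)$,
which cannot return zero.

Because the corrections are label-free, each subject's corrected matrix is
computed once and reused across permutations. Re-tuning $C$ inside every
permutation is available (`retune = TRUE`), but the default *fast mode*
fixes each subject's $C$ at the value tuned on the observed labels; under
the null the tuned-C and fixed-C accuracy distributions coincide, and the
acceptance tests confirm the empirical type-I error of the fast mode
matches the nominal 5% level. The permuted pipeline runs in compiled code;
its balancing/splitting draws use a dedicated seeded generator, so results
are reproducible from the seed alone.

## Scenario design

`run_scenario()` packages the dissociation logic: simulate a study, run
the pipeline under corrections {none, mean-signal, response-time}, and
report the per-correction significance verdicts.

| scenario | injected signal | raw | mean-proj. | RT-resid. |
|---|---|---|---|---|
| `null` | none | ns | ns | ns |
| `pattern_driven` | zero-mean patterns | sig | sig | sig |
| `mean_driven` | uniform offset (pair) | sig | **ns** | sig |
| `rt_driven` | RT gain × condition RT gaps | sig | (not graded) | **ns** |

`rt_driven` carries its condition signal entirely through RT: conditions
differ in RT means (as observed behaviorally) and a global RT-amplitude
gain converts that into amplitude differences. RT residualization removes
it by construction. The mean-projection cell of this scenario is not
graded: with near-uniform baselines the voxel-mean direction almost
coincides with the uniform RT loading, so mean projection *also* removes
most of this signal — a property of the construction, not of the
correction under study.

**Effect-size defaults** were calibrated during development so that raw
decoding lands modestly above chance (about 58–63% at these problem sizes)
rather than at ceiling: `pattern_effect = 0.8`, `mean_effect = 0.16` on
the pair condition, `rt_coupling = 0.01` per ms. Two considerations set
this level. Below ceiling, the corrections and the permutation machinery
are exercised in the regime where published MVPA effects actually live;
at the same time the verdict-recovery property needs each "significant"
cell to be adequately powered at 17 subjects and 32 test trials, which a
52–55% true accuracy cannot deliver (the one-sided power of the group test
at that level is only ~0.5–0.7). The defaults therefore sit at the lowest
level that keeps expected cell-wise verdict recovery above 90%.

A structural note on `rt_driven`: with the behavioral RT means separated
by ~100–200 ms and a trial-level RT SD of 300 ms, the RT-mediated class
separation is capped at $d' \approx 0.5$ *regardless of coupling strength
or noise level* — the conditions' RT distributions simply overlap too
much. Raw decoding in this scenario therefore tops out near 55%, and its
"significant" verdict is the least powered cell of the matrix.

**Inference defaults** are desk-scale: `n_perm = 200` permutations per
correction in scenario runs (3000 is the convention for a single
confirmatory analysis and is available by argument), fast-mode fixed-C
permutations, 17 subjects, 40 voxels, 80 trials per condition. The
acceptance suite runs 20 seeded repetitions of all four scenarios and
requires ≥90% of graded cell verdicts to match the table above; with
exact per-cell calibration at $\alpha = 0.05$, five truly null cells flip
significant at ~5% each, so *per-repetition* recovery of the full matrix
is mathematically capped near $0.95^5 \approx 77\%$ — the cell-wise
criterion is the one a correctly calibrated pipeline can and should meet
(expected ≈ 96–97%).

## What the simulation does and does not show

The generator emulates the statistical skeleton of a three-condition
retrieval experiment: design counts, condition RT distributions, and the
three signal routes a linear classifier could exploit. It deliberately
omits spatial autocorrelation, motion and physiological noise,
scanner drift (in the amplitude path), trial-to-trial amplitude
variability beyond Gaussian noise, and any encoding-phase structure.
Passing the scenario suite shows that the *pipeline* is calibrated and
that the corrections are selective for their intended signal components;
it does not certify region-specific biological claims, and real-data
accuracies from any particular study are not recoverable without the
original scans.

## Numerical choices and degenerate inputs

* Projection contracts are asserted at 1e-8 relative tolerance;
  `corrected_matrix` objects carry their residual-orthogonality
  diagnostics.
* Zero mean pattern or zero RT variance → identity correction with a
  warning, not an error.
* Single-class cross-validation folds are scored on the labels available
  (with a once-per-session warning); if all folds are degenerate, tuning
  aborts.
* Tied CV accuracies, including the all-tied case at extreme
  regularization, resolve to the smallest $C$.
* SVM decision ties (decision value exactly zero, typical at
  $C = 10^{-10}$ where the weight vector vanishes) predict the negative
  class; on balanced test sets this yields exactly 50%.
* Zero-variance features receive unit scale during standardization.
* Seeds: every stochastic step (trial tables, patterns, down-sampling,
  splitting, permutations) derives its own stream from user-visible seeds
  via a fixed mixing function; identical inputs give bit-identical
  outputs.

## Problem sizes used in the validation suite

Chance calibration averages 200 null subjects at the full design; type-I
error uses 100 group analyses of 8 subjects × 60 trials at 200
permutations; dissociation recovery uses 20 repetitions × 4 scenarios × 3
corrections at the scenario defaults above; the GLM round trip uses 2-run
designs with up to 136 trials. These sizes put Monte-Carlo error
comfortably inside each criterion's tolerance while keeping the whole
suite in the minutes range on one CPU.
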