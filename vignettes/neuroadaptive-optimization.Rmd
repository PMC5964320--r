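---
title: "Neuroadaptive Bayesian optimization: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuroadaptive Bayesian optimization: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldopt)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters with their
defaults and rationale, what the synthetic-data generator does and does
not emulate, the numerical choices, and the open design decisions we
resolved. No empirical claim is made here beyond what the package's tests
and `scripts/acceptance.R` themselves compute.

## 1. The closed loop

A closed-loop run alternates two stages. In the *data-modeling* stage,
the contrast of every completed task block is (re-)estimated by an
incremental GLM and the full set of (task coordinates, contrast) pairs
conditions a Gaussian-process surrogate. In the *guided-search* stage,
the expected-improvement acquisition function picks the next task from
the discrete candidate set. The first five blocks are a random burn-in
(uniform draws without replacement — this maximizes early coverage of the
space; with fewer candidates than burn-in blocks the remainder is drawn
with replacement); the first GLM runs once the burn-in completes.

### Experiment spaces

Two space constructors cover the study designs we emulate:

* `task_space_from_probabilities()` — each of 16 cognitive tasks sits at
  the coordinates given by its probability of recruiting two brain-network
  components, so the space is the unit square and the coordinates carry
  meta-analytic meaning. The tasks are placed at raw probabilities (not
  rescaled): the bounds are naturally $[0,1]^2$ and rescaling would
  distort the interpretation of lengthscales.
* `task_space_parametric()` — full factorial grids over one or two
  parametric manipulations (16 difficulty levels; 8 step counts × 2
  convolution conditions), with each dimension mapped linearly onto
  $[0,1]$ so that a single lengthscale prior scale is meaningful across
  spaces.

Candidates are sorted lexicographically by id at construction and every
downstream argmax breaks ties toward the lowest candidate index, making
all searches deterministic given a seed.

The recruitment probabilities shipped in
`inst/extdata/synthetic_task_probabilities.csv` (and embedded in
`make_fixture()`) are **synthetic illustrative values**: they reproduce
the qualitative layout of executive-function meta-analyses (planning and
reasoning tasks load the dorsal frontoparietal network, inhibition and
listening tasks the ventral one) but are not estimates from any published
meta-analysis.

### Target measure

The per-block contrast is computed from incremental GLMs fit separately
per ROI timecourse. The design matrix after $k$ blocks contains:

* one HRF-convolved regressor per completed block of interest,
* one pooled regressor per nuisance event *class* (all 5 s instruction
  periods share a column; likewise response intervals). Per-block
  nuisance columns would nearly double the design for no identifiable
  gain, so pooling is the conventional reading;
* six motion parameters, a linear trend, and an intercept.

All betas are refreshed every iteration, so the GP training set at
iteration $k$ holds the *latest* re-estimate of all $k$ contrasts
(`refresh = TRUE`); an append-only mode (`refresh = FALSE`) is available
for comparison. On noiseless, orthogonalized designs refreshing leaves
earlier blocks' contrasts unchanged — a property the tests verify.

### Surrogate model

Zero-mean GP, squared-exponential kernel with one lengthscale per
dimension (ARD; a single shared lengthscale for 1D spaces), white
observation noise. Hyperparameters are chosen by Type-2 maximum
likelihood (multi-restart L-BFGS-B on log-parameters, bounded) on pilot
data and then held fixed for all closed-loop runs; group-level and
voxel-level analyses retune on their own data. `make_fixture()` pre-tunes
on three seeded pilot traversals of the candidate set, mirroring tuning
on independent pilot subjects.

### Acquisition

Expected improvement in closed form with
$z = (m(x) - f_{\max})/\mathrm{std}(x)$. We deliberately use the
predictive *standard deviation* in the denominator: the variance form
that sometimes appears in print is dimensionally inconsistent with the EI
closed form, and the standard-deviation form is the standard definition.
$f_{\max}$ is the maximum predicted mean over the candidates by default
(`max_predicted`); `max_observed` is available and yields more
exploratory behaviour when observations are noisy. The acquisition argmax
is restricted to the candidate set — those are the only runnable tasks —
while dense-grid predictions are used for maps and plots only.

## 2. The synthetic scanner

`simulate_run()` generates, per ROI,

$$y_t = \sum_b a(\text{roi}, \text{task}_b)\, r_b(t) +
\delta\, t + \varepsilon_t + s_t,$$

with $r_b$ the HRF-convolved block regressor, $a$ the ground-truth
activation amplitude (arbitrary BOLD units), $\delta$ a linear drift per
frame, $\varepsilon_t$ white Gaussian noise, and $s_t$ optional additive
Gaussian spikes at a per-frame rate (the spike model is intentionally
simple — its only job is to exercise the despiker). Motion is a smooth
six-parameter random walk; simulated voxels equal their parent ROI's
noiseless signal plus independent voxel noise. Ten lead-in frames model
T1 equilibration and are discarded by every consumer, mirroring the
acquisition protocol. Everything is reproducible bit-for-bit from the
seed.

Protocol timing: `exp1`/`exp3` blocks are 5 s instruction + 3 s rest +
35 s task + 19 s rest = 62 s; `exp2` blocks are 30 s problem + 5 s
response + 19 s rest = 54 s, at TR = 2 s. Twenty `exp1` blocks give
20.67 min and twenty `exp2` blocks give 18 min, which the acceptance
script verifies. The 19 s `exp2` rest is not stated explicitly in the
protocol description we emulate but is forced by the printed 18-minute
run length. For the 15-block `exp3` protocol our arithmetic gives
15 × 62 s = 15.5 min; the printed 15.67 min presumably includes extra
lead-in time, and we note rather than resolve the 10-second discrepancy.

What the generator does **not** emulate: k-space physics, registration
or smoothing artefacts, spatially autocorrelated noise beyond shared ROI
signal, physiological (cardiac/respiratory) confounds, and
non-stationary noise. Passing tests therefore demonstrate correctness of
the estimation machinery under the stated noise model, not robustness to
every artefact of real scanner data.

### Despiking

The real-time pipeline removes large signal spikes with a scalar
local-level Kalman filter (innovation gating at `gate = 3` innovation
SDs; observation noise estimated robustly from first differences,
state-evolution variance `q_ratio = 1` times the observation variance).
A gated frame whose deviation *persists into the next frame in the same
direction* is accepted as a genuine signal change and the state
re-initializes on it; only non-persistent excursions are replaced by the
filtered prediction. Without the persistence rule a filter of this kind
flattens steep hemodynamic ramps whenever the evoked response dwarfs the
background noise, biasing block betas toward zero — the tests pin this
behaviour. Non-flagged frames pass through exactly unchanged.

### Run-quality rules

Offline analyses scrub frames with framewise displacement above 1.5 mm
(Power-style FD: summed absolute differences of translations plus
rotations converted on a 50 mm sphere) and exclude outlying runs with an
iterative two-sided Grubbs test at $\alpha = 0.05$ using the t-based
critical value.

## 3. Group level and inference

`group_map()` pools all observations of all runs, retunes the GP by
Type-2 ML and predicts over candidates and a dense grid. The map is
invariant to observation order.

`quadratic_trend_test()` compares nested linear mixed-effect models
(per-subject random intercept only — the data do not identify richer
structures at these sizes; ML fits, not REML, since fixed effects are
compared) with a likelihood-ratio test. With a single parametric
dimension the quadratic model adds one term (LRT df 1); with a second
categorical factor both models carry the factor's main effect and its
interaction with the linear term, and the quadratic model adds the
squared term plus its interaction with the factor (df 2). Singular fits
are reported in the result, not silently dropped.

`voxel_prediction_maps()` repeats the analysis per voxel on scrubbed,
linearly detrended data: per-voxel GLM betas are contrasted against the
reference ROI's betas, fed into a per-voxel GP (Type-2 ML with a reduced
restart count of 2 for speed — exposed as an argument), and predicted
over the candidates. `spatial_similarity()` correlates each voxel's map
with a reference map across candidates, Fisher-z transforming with $r$
clipped to $\pm(1 - 10^{-7})$ so that perfectly correlated voxels stay
finite and averageable. Registration to a standard space is replaced by
identity mapping on the synthetic voxel grids.

`tmax_permutation()` corrects cluster-level inference for multiple
comparisons with the sign-flip null of the maximum statistic: exhaustive
enumeration of all $2^n$ assignments when $2^n \le 2^{16}$, Monte-Carlo
with the identity assignment always included otherwise, so corrected
p-values never fall below $1/B$. One-sample tests are two-tailed (max of
$|t|$), and the paired comparison of group-derived versus hypothesized
similarity maps is the one-sample test on per-cluster differences —
two-tailed as well. All-zero clusters carry no evidence and are kept
with $t = 0$; zero-variance clusters around a nonzero mean leave $t$
undefined and are dropped with a warning. Cluster masks are supplied as
labels (defaults: minimum 200 voxels per cluster, mirroring the usual
network-thresholding conventions); forming clusters from continuous
statistical maps is out of scope.

## 4. Numerical choices

* Convolution at 0.1 s microtime, sampled at the TR, via FFT padded to a
  power of two; discretization error is negligible against all test
  tolerances, and a brute-force discrete-summation oracle pins the
  result.
* HRF: difference of two gamma densities (peak delay 6 s, undershoot
  delay 16 s, unit dispersions, peak:undershoot ratio 6), scaled to unit
  peak — the de facto canonical parameterization, exposed as arguments.
* GLM: minimum-norm least squares via SVD with a relative singular-value
  tolerance, so rank-deficient designs (e.g. an all-zero motion trace in
  noiseless simulations) remain analyzable instead of erroring.
* GP: Cholesky factorization with a 1e-10 jitter escalating by decades on
  failure; posterior variances clamped at zero.
* Fisher z clipping at $|r| = 1 - 10^{-7}$.
* All argmax tie-breaks resolve to the lowest candidate index in the
  deterministic id ordering.
* Every stochastic component draws from an explicit integer seed through
  a private RNG stream that restores global RNG state.

## 5. Study conditions and problem sizes

The canonical fixtures fix the simulated study conditions once:

* `exp1_like` — 16 tasks, 2D, 4 ROIs, 20 blocks, pairwise dFPN > vFPN.
  Activation amplitudes are 5 BOLD units per unit recruitment
  probability, placing the true optimum (3.0) 0.5 units above the
  runner-up on an adjacent task. The BOLD noise SD is derived so that
  this margin equals exactly 2 per-block contrast-noise SDs under the
  full design (the noise propagation is computed analytically from the
  design's normal equations).
* `exp2_reasoning` / `exp2_tol` — plateauing quadratic profiles peaking
  near the upper difficulty levels / at 6–7 steps, no convolution
  effect; noise keyed to a tenth of the surface range, since smooth
  surfaces have near-tied neighboring levels and a margin-based rule
  would degenerate.
* `exp3_like` — the 16-task space with a one-versus-mean contrast over
  four ROIs and 15 blocks.

Validation problem sizes (chosen as the smallest sizes at which the
binomial/Monte-Carlo error of each check is well below its acceptance
band): closed-loop recovery over 200 seeded runs of 20 iterations;
family-wise error of the tmax correction over 1000 null replicates of a
10-subject × 5-cluster design; trend-test calibration and power over 200
replicates each of 10 subjects × 16 levels; EI versus a $10^6$-draw
Monte-Carlo oracle; GP posteriors versus dense-inverse oracles on
problems of up to 8 points; back-projection separation over 40 seeds
with 2 runs, 12 blocks and 8 voxels each.

## 6. Known limitations

* The GP assumes stationary, isotropic-per-dimension smoothness; strongly
  non-stationary activation surfaces would call for a different kernel.
* The incremental GLM is ordinary least squares without prewhitening;
  temporal autocorrelation of real BOLD noise is not modeled (and not
  simulated).
* No online stopping criterion: runs have a fixed iteration budget.
* The mixed models use a random intercept only; random slopes at these
  data sizes routinely produce singular fits.
* Acquisition is expected improvement only; no alternative acquisition
  functions are provided.
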