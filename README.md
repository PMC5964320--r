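# boldopt

Closed-loop **neuroadaptive Bayesian optimization** of fMRI experiments, in R.

## The problem

Which cognitive task best dissociates two brain networks — say, elicits the
largest BOLD contrast between the dorsal and ventral frontoparietal networks
(dFPN, vFPN)? Testing every candidate task exhaustively in the scanner is
prohibitively expensive. A closed-loop alternative treats the scanner as the
evaluator inside a Bayesian optimization loop: tasks live at coordinates in a
low-dimensional *experiment space*, a Gaussian-process (GP) surrogate model
maps task coordinates to the expected network contrast, and an acquisition
function picks the most informative task to run next. After a short random
burn-in the loop alternates between (1) re-estimating the contrast of every
completed block with an incremental GLM and (2) selecting the next task by
expected improvement, so the experiment spends its limited scan time on the
most promising regions of the task space.

`boldopt` implements this pipeline end to end on simulated data: a
block-design BOLD simulator with a known ground-truth activation surface
stands in for the scanner, so every stage — real-time despiking, incremental
GLM, GP surrogate, acquisition, group maps, voxel-wise back-projection and
permutation inference — can be validated against ground truth. The package
is aimed at methods researchers who want a tested reference implementation
of the adaptive-design machinery, and at experimenters who want to simulate
a planned closed-loop study before scanning.

## The model

**Target measure.** After each block $k$, an incremental GLM is refit per
network ROI: one regressor per completed task block (35 s boxcar convolved
with the canonical double-gamma HRF), a pooled nuisance-event regressor,
six motion parameters, a linear trend and an intercept. The per-block
target measure is the contrast of block betas,
$c_k = \beta_k(\text{dFPN}) - \beta_k(\text{vFPN})$ (or the target minus
the mean of several comparison networks).

**Surrogate.** A zero-mean GP with squared-exponential (ARD) kernel

$$k(\mathbf{x}, \mathbf{y}) = \sigma^2 \exp\left\{-\tfrac12 \sum_d
\frac{(x_d - y_d)^2}{l_d^2}\right\},$$

white observation noise $\sigma_{\text{noise}}^2$, and hyperparameters
tuned by Type-2 maximum likelihood on pilot data, then fixed in the loop.

**Acquisition.** Expected improvement over the current best $f_{\max}$
(maximum predicted, or maximum observed, value):

$$EI(\mathbf{x}) = (m(\mathbf{x}) - f_{\max})\,\Phi(z) +
\mathrm{std}(\mathbf{x})\,\phi(z), \qquad
z = \frac{m(\mathbf{x}) - f_{\max}}{\mathrm{std}(\mathbf{x})},$$

maximized over the discrete candidate set.

**Post hoc.** Group-level GP prediction maps pool all subjects'
observations; linear-vs-quadratic mixed-model likelihood-ratio tests probe
parametric trends; voxel-wise back-projection repeats the analysis per
voxel, correlates each voxel's prediction map with a reference map
(Fisher-z), and tests cluster means with sign-flip max-statistic (tmax)
permutation correction.

## Worked example

```r
library(boldopt)

fx <- make_fixture("exp1_like", seed = 1)   # canonical 16-task study
fx
#> Synthetic experiment fixture 'exp1_like'
#>   16 candidates (2D), protocol exp1, 20 blocks
#>   contrast: dfpn > vfpn
#>   planted optimum: tower_of_london (margin 0.5 = 2 contrast-noise SDs)

run <- bo_run(fx$space, fx$truth, fx$hyper, fx$target, fx$others,
              n_iterations = 20, burn_in = 5, seed = 7)
summary(run)
#> Closed-loop run summary
#>   modal closed-loop task: tower_of_london
#>   planted optimum:        tower_of_london
#>   best observed contrast: 3.453
#>   mean successive distance: 0.04103
#>   sampling frequencies (closed loop):
#>            tower_of_london       counting_calculation ...
#>                          1                          0 ...
```

The fixture plants a 16-task 2D space whose true best contrast
(`tower_of_london`, 3.0 BOLD units) beats the runner-up by 0.5 — twice the
per-block contrast noise SD. After the 5-block random burn-in the loop
samples the planted optimum on every closed-loop iteration here, and the
shrinking distance between successive choices (`mean successive distance`)
marks the explore-to-exploit transition. `group_map()` pools several runs
into a group-level prediction surface, and `voxel_prediction_maps()` +
`tmax_permutation()` reproduce the post-hoc inference stages.

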