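---
title: "Methods: group spatial ICA of n-back working-memory fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group spatial ICA of n-back working-memory fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

`nbackica` implements a complete analysis chain for blocked letter n-back
fMRI: functional networks are extracted by temporal-concatenation group
spatial ICA (infomax, stabilized across randomized restarts), each subject's
network time courses are obtained by back-reconstruction and regressed on a
GLM design built from three hemodynamic basis functions, the three basis
coefficients per condition are collapsed into a single area-under-the-curve
(AUC) activation value, and the *BOLD load effect* (2-back minus 0-back
activation) is carried into a mixed repeated-measures ANOVA, post-hoc
t-tests, age-by-activation interaction regressions, Spearman correlations,
and a Fisher r-to-z comparison of correlations between age groups. Because
no imaging cohort ships with the package, a synthetic-data module generates
fMRI-like and behavioral data with the statistical structure the chain
assumes, and every stage is validated against that ground truth.

## Task model

The paradigm is a blocked letter n-back with three load conditions (0-back,
1-back, 2-back), each presented in two blocks of 100 trials (600 trials
total). Stimuli last 0.5 s with inter-trial intervals uniform on 1–2 s, so a
block spans roughly 200 s — about 100 scans at the TR of 2 s, or ~200 task
scans per condition. Letters come from an 18-consonant alphabet (no Q, Y,
J); the 0-back target is the letter X; in the memory conditions a target
repeats the letter shown n trials earlier, ignoring case. `build_schedule()`
enforces several choices the task description leaves open:

* **Exact target counts.** Targets occur in half of the trials of every
  block. We place exactly `round(0.5 * 100)` targets rather than sampling
  each trial independently, which makes the target fraction testable rather
  than a random variable.
* **Unique ground truth.** Non-target letters are constrained never to
  satisfy the n-back rule by accident, so the `is_target` flag is the unique
  correct answer key.
* **Semi-random block order** is read as: each condition appears once in the
  first half of the run and once in the second half, in random order within
  halves.
* **Inter-block rests** of 20 s (configurable) separate blocks and precede
  the first one; task regressors are implicitly contrasted against these
  rest spans. The source text gives no inter-block timing.
* Events enter the GLM as 0.5 s boxcars at trial onsets. At a TR of 2 s the
  difference between a 0.5 s boxcar and an impulse is negligible, but the
  boxcar matches the stimulus duration.

## HRF basis set and design matrix

`canonical_hrf()` is the conventional double-gamma: a gamma density peaking
near 5 s minus one sixth of a gamma density peaking near 16 s, on a 32 s
support, scaled to unit peak. The source analysis names the canonical HRF
and its two derivatives without parameterizing them, so the package uses the
field-standard parameters (delays 6 s and 16 s, unit dispersions, ratio
1/6). The temporal derivative is the backward finite difference with respect
to a 1 s onset shift; the dispersion derivative is the finite difference
with respect to the response-dispersion parameter with increment 0.01. Both
derivatives share the canonical's normalization so all three coefficients
live on one scale.

`build_design()` assembles, per subject: 3 conditions x 3 bases, the six
motion parameters and their first differences (backward difference with a
leading zero) each convolved with the three bases (36 columns), and a
constant — 46 regressors. Convolving motion regressors with HRF bases is
unusual, but it is what the modeled analysis states; `convolve_motion =
FALSE` provides the conventional 22-column alternative. All columns except
the constant are mean-centered. No high-pass filter is applied: slow drift
is part of the noise model and the centering plus drift-shaped nuisance
variance is left to the residual. The design's condition number is reported
and a warning is raised above 1e6 (an all-zero condition, for example,
guarantees rank deficiency).

Convolution is carried out on a 0.5 s grid (the basis `step`, which must
divide the TR) and sampled at scan times, so a unit event at scan 0
reproduces the sampled canonical curve exactly.

## Group spatial ICA

`run_group_ica()` follows the temporal-concatenation recipe:

1. **Per-subject temporal PCA** to `k_subject` components (default 1.5x the
   model order, capped at the scan count *and at the smallest per-subject
   numerical rank* — noiseless task data have rank as low as the number of
   condition regressors, and requesting more raises an error in
   `reduce_group()`).
2. **Concatenation** of the reduced subjects along the reduced-time axis and
   **group PCA** to `k_group` (default = number of components), whitened for
   ICA.
3. **Infomax** with the logistic nonlinearity — the natural-gradient update
   `W <- W + lrate (I + (1 - 2 g(u)) u') W` over randomized sample blocks.
   The initial learning rate is `0.005 / ln(k)`; the rate is annealed by 0.9
   whenever the update direction turns by more than 60 degrees; weights that
   blow past 1e8 trigger a colder restart. Convergence is declared when the
   *relative* weight change `||dW||/||W||` falls below 1e-6 (infomax inflates
   the absolute weight scale for very sparse sources, so an absolute
   criterion would stall); 512 sweeps is the cap, beyond which a condition
   carrying the partial result is raised.
4. **Stability analysis**: the decomposition is re-run 10 times (the study
   default) with distinct seeds; all pooled component maps are clustered by
   1 − |correlation| with average-linkage agglomeration into k clusters.
   Each cluster's centrotype (the member with the largest summed
   within-cluster similarity) becomes the reported component, and the
   stability index is the mean within-cluster |correlation| minus the mean
   between-cluster |correlation|. Note that even duplicated runs do not give
   an index of exactly 1, because between-cluster correlations are small but
   not zero.
5. **Back-reconstruction** through the pseudo-inverse of the composed
   pipeline: subject maps `S_i = W D^{-1/2} H_i' G_i' X_i'` and time courses
   `A_i = G_i H_i D^{1/2} W^{-1}`. Subject maps sum across subjects exactly
   to the group maps.

Fixed conventions make the decomposition reproducible: components are
ordered by explained variance (descending), each map is sign-flipped so its
largest-magnitude voxel is positive (the time course flips along, keeping
the product invariant), and stored maps and time courses are z-scored.
Whether z-scoring happened before or after back-projection in the original
toolchain is ambiguous; it is applied after, at both levels.

Model order estimation (`estimate_order()`) is Gaussian-source MDL on the
nonzero eigenvalue spectrum of the data covariance with the i.i.d. sample
count set to the number of scans; eigenvalues below 1e-10 of the largest are
ridged up to that floor so exact-rank inputs are handled. On group data the
median of per-subject estimates is returned.

Component selection, a visual step in the original workflow, is replaced by
template matching (`select_components()`): each template picks the component
with the largest absolute spatial correlation, thresholded at 0.3.
Sub-threshold templates are reported unmatched rather than force-assigned,
duplicate assignments raise unless a manual override is given.

## Activation statistic

For each subject, component and condition the three basis coefficients are
collapsed as

AUC = (b_can * sum(canonical) + b_td * sum(time_deriv) + b_dd * sum(disp_deriv)) / sum(canonical),

i.e. the summed reconstructed response normalized by the summed canonical
HRF. "Area under the curve" is read as the discrete sum over the basis
support; the normalization is fixed by the formula's own denominator. When
the derivative sums vanish the statistic equals the canonical coefficient,
and it is linear in all three coefficients. A basis whose canonical sums to
zero (or negative) is rejected rather than silently sign-flipped. Because
the AUC is an area measure, a subject whose response is delayed and widened
relative to the canonical model is scored by the area of their actual
response: the statistic absorbs latency shifts that bias a canonical-only
coefficient.

Incorrect-response events deliberately remain in the condition regressors.
The BOLD load effect is the AUC difference, 2-back minus 0-back, per subject
and component. Time courses entering the regression are the z-scored
subject-level component time courses, consistent with the z-scoring of the
decomposition; activation values are therefore on a standardized scale in
the pipeline (ground-truth recovery tests that need absolute amplitudes fit
the raw source time courses instead).

## Behavior

Responses faster than 200 ms or slower than 1500 ms are marked incorrect —
trials are never dropped, so accuracy denominators are untouched, and the
boundary values are valid ("faster"/"slower" read strictly). Missing RTs
count as incorrect. Accuracy is correct/total per condition; the RT summary
is the median over correct valid trials; a subject with no correct trials in
a condition has an undefined median and is flagged (a hard error is
available via `on_empty = "error"`, but aborting a whole cohort for one
degenerate subject is rarely what a caller wants).

The efficiency indices are `speed_cost = (RT2 - RT0)/RT0` and
`accuracy_cost = (acc0 - acc2)/acc0`; both are unitless. Whether published
group costs are means of per-subject ratios or ratios of group means is not
stated; the package computes per-subject ratios in the pipeline and exposes
`cost_from_means()` for the group-mean arithmetic (the two agree to two
decimals at the published values).

Exclusion for below-chance performance (< 0.50 accuracy, strict) is applied
disjunctively over the 1-back and 2-back conditions by default — the
conservative reading — with the conjunctive reading available via
`rule = "both"` (the single excluded participant in the modeled cohort met
both).

## Statistics

* `rm_anova()`: mixed design with component as within-subject factor and age
  group as between-subjects factor, via `aov()` with an `Error(subject /
  component)` stratum. With k components and N subjects the interaction has
  dfs `(k-1, (N-2)(k-1))` — (7, 511) at 38 + 37 subjects and 8 components. A
  Greenhouse–Geisser epsilon computed from the pooled within-group
  covariance accompanies the uncorrected p.
* `load_ttests()`: pooled-variance two-sample t (the published dfs, e.g.
  t(73) at 38 + 37, imply pooling) and one-sample t per group. Zero-variance
  cells are flagged; zero variance with a nonzero mean difference raises.
* `interaction_regression()`: age effect-coded (second factor level +1) and
  centered — with unbalanced groups the centered codes are deliberately not
  ±1 — predictor z-scored within group (which makes the model invariant to
  affine rescaling of the raw predictor), outcome regressed on age,
  predictor, and their product. Reported dfs follow the conventional
  n − p − 1; the published t(74)/F(3,74) at n = 75 with three predictors is
  inconsistent with that convention and is not imitated.
* `spearman_rho()` uses average ranks for ties; `compare_correlations()` is
  the Fisher/Cohen z for independent correlations,
  `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
  normal p. Applying the Fisher transform to Spearman rho is approximate;
  it is done here because that is the procedure being reproduced.
* No multiple-testing correction is applied anywhere (none was applied in
  the modeled analysis); all p-values are two-sided.
* `analysis_report()` runs the chain in order and emits both outcome
  variants (costs and per-condition raw accuracy/RT) wherever the original
  description is ambiguous about which fed a given model.

## What the synthetic data emulate — and what they do not

`simulation_config()` defaults encode the study conditions: TR 2 s, ~200
task scans per condition, two groups ("young", "old") of 38 subjects,
behavioral distributions parameterized by the published group means/SDs of
median RT and accuracy per condition (`behavior_parameters()`).

* **Spatial sources** are Gaussian blobs at mutually separated centers
  (separation 3 sigma, default sigma 1.5 voxels), hard-thresholded to
  sparsity and scaled to unit Euclidean norm. Spatial ICA assumes sparse,
  super-Gaussian sources; blobs are the simplest generative model with that
  property. Pairwise |spatial correlation| stays below 0.3.
* **Condition amplitudes**: each source gets a positive baseline (uniform
  0.3–0.7) plus a graded load effect (uniform 0.3–1.0, 1-back halfway
  between 0-back and 2-back), with between-subject Gaussian variation (SD
  0.2). All planted sources are load-positive; negative-load networks exist
  in real data but add nothing to the recovery tests.
* **HRF variability**: per-subject Gaussian jitter (SD 0.5 s by default) on
  both gamma delays, 1.5x larger in the old group — the very variability the
  derivative bases exist to absorb. Each subject's HRF is peak-normalized,
  so a delayed, wider response carries more area; the AUC statistic scores
  that area, which recovery tests account for.
* **Noise and drift**: white Gaussian voxel noise plus low-order cosine
  drift (3 terms, per-voxel random coefficients). Motion nuisance series are
  smoothed random walks. There are no spikes, no physiological noise, no
  spatial noise correlation, no EPI distortion: passing recovery tests shows
  the estimator chain is correct, not that it is robust to every artifact of
  real acquisitions.
* **Behavior**: trial RTs are lognormal around a subject-level median (drawn
  from the group mean/SD), truncated to the valid range for correct trials —
  lognormal because RTs are positive and right-skewed; only means/SDs/
  medians are published. Correctness is Bernoulli at a subject-level
  accuracy. Out-of-range RTs (< 200 or > 1500 ms) are planted only on
  already-incorrect trials, mirroring the rule that such responses are
  incorrect; filtering therefore never flips a correct trial and the
  generating accuracies remain recoverable. Target and non-target trials
  are generated identically (their separate statistics are not published).
* **Coupling**: in the old group's 2-back cell, subject accuracy includes
  `coupling_strength` times the z-scored amplitude of a designated source,
  with the residual between-subject SD shrunk so the total matches the group
  SD. The planted amplitude–accuracy correlation is therefore
  `coupling_strength / acc_sd(old, 2-back)` — 0.06/0.12 = 0.5 in the
  acceptance setup — attenuated slightly by binomial trial noise. The
  generator raises if |coupling| exceeds the accuracy SD or if the coupling
  term alone pushes a subject outside (0, 1); ordinary subject noise is
  clamped to [0.01, 0.99] instead, since unbounded Gaussian tails would
  otherwise crash the generator stochastically even at zero coupling.

All randomness flows from one master seed through named substreams
(`substream_seed()`), so adding a subject or reordering stages never
perturbs another stage's draws, and every generator is bit-reproducible.

## Numerical choices and degenerate inputs

* Infomax tolerance 1e-6 (relative), max 512 sweeps, annealing 0.9, identity
  initialization; sample-order permutations are the only stochastic element.
* Eigenvalue floors: 1e-12 of the largest eigenvalue when checking requested
  reduction ranks; 1e-10 ridge in MDL.
* Ties in template matching resolve to the first maximum; duplicate
  template assignments are an error by design.
* `reduce_group()` refuses ranks the (mean-removed) data cannot support;
  note that voxelwise mean removal caps the per-subject rank at scans − 1.
* Degenerate statistical inputs (constant predictors, zero-variance cells,
  empty component selections, empty cohorts) are either flagged in the
  output or raise a named error — never silently patched.

## Problem sizes used by the tests

The test and acceptance configurations are scaled-down versions of the study
conditions, chosen so the full suite exercises every stage end to end: a
12 x 12 x 8 voxel grid with 8 planted sources and 6 subjects per group for
the ICA recovery and pipeline checks (the packaged
`inst/extdata/config-small.yaml`), a 16 x 16 x 12 grid where finite-sample
ICA leakage must stay under a few percent, 40 + 40 subjects per replicate
for the coupling power (100 replicates) and test-size (500 replicates)
Monte Carlos, and 200-subject groups for calibrating the behavioral
generator against its target distributions.

## Known limitations

* OLS only: no prewhitening/autocorrelation model in the temporal
  regression, consistent with the modeled analysis.
* The Fisher z comparison on Spearman rho is an approximation.
* The generator's voxel grids carry no anatomy and the simulation has no
  spatial normalization step; `select_components()` is a programmatic
  stand-in for visual network identification, not a validated classifier.
* Single run per subject; no session or scanner effects.
* The MDL estimator inherits the known sensitivity of i.i.d. order
  selection to correlated noise; on the simulated white-noise background it
  brackets the planted rank, which is all the pipeline relies on.
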