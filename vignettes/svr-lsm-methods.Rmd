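---
title: "Multivariate SVR lesion-symptom mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate SVR lesion-symptom mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Lesion-symptom mapping asks which brain locations, when destroyed by a
stroke, drive a behavioral outcome. The inputs are per-subject binary lesion
masks registered to a common grid (here, MNI-space conventions) and one
behavioral score per subject — in the motivating application an EQ-5D-3L sum
score on 0–10, where higher means worse self-reported quality of life.
Mass-univariate approaches test each voxel separately and ignore that
lesions are spatially extended, correlated objects. The multivariate
alternative implemented here (SVR-LSM) fits a single epsilon support vector
regression over all voxels jointly and interprets the back-projected feature
weights.

# The model

## Analysis mask and flattening

Only voxels lesioned in at least `min_overlap` subjects (default 10) enter
the analysis; rarer voxels cannot support stable multivariate weights.
Subjects whose lesion misses the mask entirely are excluded and reported.
The surviving cohort is flattened into a subject-by-voxel binary matrix
$X \in \{0,1\}^{n \times p}$; columns enumerate mask voxels in R's native
column-major order (first axis fastest). Any fixed order is statistically
equivalent; the native order avoids an index permutation on every flatten
and unflatten.

## Nuisance control

Lesion volume correlates with almost every outcome, so a voxel's raw
association mixes location information with sheer size. The default control
regresses volume out of both sides by ordinary least squares:
$y$ is replaced by the residual of $y \sim 1 + v$, and each column of $X$ by
the residual of $X_{\cdot j} \sim 1 + v$. The residuals are exactly
uncorrelated with $v$ (to numerical precision), and the operation is
idempotent. Raw milliliters are regressed by default; a log-volume option
exists. The alternative "direct total lesion volume control" (each lesion
vector scaled to unit L2 norm) is available behind the same interface
(`method = "dtlvc"`), with the regression default matching the motivating
analysis.

## Epsilon-SVR and the feature-weight map

The residualized data are fit by epsilon-SVR with the RBF kernel
$k(a,b) = \exp(-\gamma \lVert a-b \rVert^2)$, solving the standard dual with
box constraint $C$ and tube width $\epsilon$. The voxelwise feature weight
is the back-projection of the dual solution onto voxel space,

$$\beta_j \;=\; \sum_{i \in SV} \alpha_i \, X_{ij},$$

with signed dual coefficients $\alpha_i$ summing to zero. Positive
$\beta_j$ means lesion status at voxel $j$ pushes the predicted score up
(worse outcome). No feature scaling is applied beyond residualization:
binary-derived residual columns are already commensurate.

## Hyperparameters

* `epsilon = 0.1` — the convention of published SVR-LSM toolboxes.
* `gamma` — median heuristic $1/\mathrm{median}\,\lVert x_i-x_j\rVert^2$,
  scale-free and standard when the width is not tuned.
* `C` — Cherkassky–Ma heuristic $\max|\bar y \pm 3 s_y|$. This deviates
  deliberately from the fixed constant $C = 30$ used by the MATLAB toolbox
  lineage. On volume-residualized scores (standard deviation around 2) a box
  of 30 is effectively no constraint: the fit interpolates its training
  data, the permuted-data refits do the same, the permutation null of
  $\beta$ inherits heavy tails, and mapping power collapses. Scaling $C$ to
  the response restores the regularized regime. The constant triple
  (C = 30, median-heuristic gamma, epsilon = 0.1) is retained as the
  reference point of the hyperparameter search, whose contract is to never
  select anything worse.
* Cross-validated search — a seeded Latin-hypercube sweep of
  $(\log C, \log\gamma, \log\epsilon)$ within bounds, followed by local
  refinement in shrinking boxes; 20 folds and 200 evaluations by default,
  deterministic given the seed. The folds are stratified by response
  quantile so each fold spans the score range.

A caution that the validation experiments made measurable: hyperparameters
minimizing cross-validated prediction error are not the hyperparameters
maximizing voxel-level mapping sensitivity. The optimizer reliably drifts to
large $C$ and small $\gamma$, which predicts well and localizes poorly. The
pipeline therefore runs inference at the fixed heuristic defaults unless
optimization is explicitly requested (`svr$optimize`, on by default for
fidelity to the published procedure); users who optimize should know the
trade-off.

## Permutation inference

With hyperparameters held fixed, the behavior vector is randomly permuted
$B$ times (default 10000) and the SVR refit each time; the kernel depends
only on $X$ and is computed once. The voxel p-value is the one-sided
add-one rank toward positive weights,

$$p_j = \frac{1 + \#\{b : \beta_j^{(b)} \ge \beta_j\}}{B + 1},$$

so $p_j \ge 1/(B+1)$ and never 0. Significance is $p_j \le \alpha$ with
$\alpha = 0.005$. The inclusive comparison matters only at desk scale: at
$B = 10000$ it selects exactly the voxels a strict rule selects (both reduce
to a count of at most 50), while at the reduced $B = 199$ used in the
validation suite a strict rule would be unattainable by construction
($\min p = 1/200 = \alpha$ exactly).

Cluster inference uses the permutation max-statistic: significant voxels are
grouped into connected components (26-connectivity by default; 6 and 18
available), and each permuted map is thresholded *at its own rank within
the pooled set of B + 1 maps, self excluded* — the identical rule the
observed map faces — producing one maximum suprathreshold cluster size per
permutation. The pooled construction keeps all B + 1 maps exchangeable
under the null; without it no permuted voxel could ever attain the floor
rank and the null would degenerate. The cluster-extent FWE p-value is again
the add-one estimator against these maxima. Clusters larger than 50 voxels
are reported with center-of-mass world coordinates (one decimal) regardless
of significance, flagged at FWE $\alpha = 0.05$; component labels are
ordered by decreasing size with ties broken by the smallest linear voxel
index.

Every permutation draws from its own seed-derived substream, so results are
bit-identical regardless of execution order or worker count; the pipeline
itself is serial.

## Tract intersection certainty

For a probabilistic tract map $T$ and the union $U$ of reportable clusters,
the certainty that the tract crosses the union is
$\max_{v \in U} T(v)$ — if any cluster voxel belongs to the tract with
probability $q$, the tract intersects the cluster with certainty at least
$q$. Tracts above 90% (strict) are flagged; certainties are also reported
as integer percentages. The union is global across hemispheres; laterality
is handled by tract naming. Maps delivered on a 0–100 scale are rescaled
with a warning. The union is restricted to clusters above the 50-voxel
reporting size, matching the cluster report.

# The synthetic cohort generator

Real acute-stroke cohorts of this kind are not publicly deposited, so the
package carries a generator whose defaults emulate the published cohort
structure and make every stage testable:

* **Volumes.** Lesioned-voxel counts are lognormal with defaults solved
  from a target median of 3.3 ml and IQR 1.1–16.9 ml at 2 mm isotropic
  voxels (`meanlog = log(412.5)`, `sdlog ≈ 2.02`), capped at 25% of the
  grid. A 1000-subject sample reproduces the median within 20%.
* **Shapes.** Each lesion grows by a random walk on the face-neighbor graph
  from a seeded center: uniformly sampled boundary voxels are absorbed until
  the drawn count is reached. Lesions are therefore always connected and
  compact-ish, mimicking infarcts; they are not biophysically realistic
  (no vascular territory geometry, no mass effect).
* **Placement.** Seed centers follow a truncated Gaussian biased toward one
  hemisphere (default center at 35% of the x-extent), emulating the
  middle-cerebral-artery concentration of trial cohorts.
* **Outcome.** The latent score is
  `intercept + effect_size * damage_fraction + volume_effect * z(log volume)
  + N(0, noise_sd)`, where `damage_fraction` is the lesioned share of a
  fixed critical region (default: a 3.5-voxel-radius sphere near the
  placement center, about 185 voxels). The observed score is the latent
  value rounded half-up and clipped into 0–10, mirroring an ordinal EQ-5D
  sum; defaults put the median near 1. An mRS-like ordinal covariate (0–6)
  is generated from the same latent with its own noise, giving the
  strong positive rank correlation such scales show in practice.
* **Seeding.** One master seed spawns per-subject substreams, so subject
  *k* is reproducible independent of cohort size; null cohorts reuse the
  identical lesions and permute the score vector under a further substream.

Two calibration helpers translate target signal strengths into generator
parameters: `noise_sd_for_r2()` (noise level at which the full linear
predictor explains a given share of latent variance) and
`effect_size_for_r2()` (effect size at which the *damage term alone*
explains a given share, accounting for the built-in damage–volume
covariance — the relevant quantity when volume is subsequently regressed
out). Because damage fraction correlates with volume by construction
(~0.7 under defaults), calibrating the joint predictor badly understates
the recoverable localization signal.

What passing synthetic tests does *not* show: performance under
registration error, segmentation noise, multi-focal lesions, cohort
heterogeneity, or score distributions unlike the simulated one. The
generator is an acceptance surface, not a claim about any trial cohort.

# Numerical and degenerate-input choices

* Binarity: values in [0, 0.5) map to 0, [0.5, 1] to 1; anything outside
  [0, 1] beyond 1e-6 is rejected (registered masks carry interpolation
  dust; genuinely non-binary maps are an error).
* Affines must agree element-wise within 1e-4 mm across the cohort.
* A response inside a single epsilon tube yields the exact degenerate
  solution (zero duals, midrange intercept) without invoking the solver.
* Overlap counting precedes the non-overlap exclusions (the two orders can
  differ; the chosen order is fixed and documented here).
* Behavior residualization precedes hyperparameter selection; the search
  sees the same residualized data the final fit sees.
* `round-half-up` (not banker's rounding) discretizes simulated scores.
* The p floor, add-one estimators and the inclusive threshold are as
  derived above; permutation counts below `1/voxel_alpha` trigger a
  warning.

# Validation problem sizes

The shipped validation suite runs at desk scale, chosen so the full suite
completes on one CPU in well under half an hour: null calibration uses 100
null cohorts (n = 120, 32³ grid, B = 199); critical-region recovery uses 20
cohorts (n = 200, damage term calibrated to 40% of latent variance,
B = 199), requiring an FWE-significant cluster with Dice ≥ 0.3 against the
true region in at least 80% of seeds; p-value uniformity pools 20 null
cohorts at B = 499. The reference configuration (B = 10000) is the
package default for real analyses.

# Known limitations

* Back-projected RBF-SVR weights have no closed-form sampling theory; all
  inference is permutation-based, and cluster inference is extent-only (no
  cluster-mass statistic).
* The method inherits SVR-LSM's known spatial displacement tendency:
  detected clusters concentrate on the most informative voxels, which can
  sit at the rim of the truly critical tissue; Dice against ground truth
  plateaus well below 1 even at strong signal.
* Voxelwise FWE (max-β) correction and FDR alternatives are out of scope.
* Single-lesion subjects are assumed by the generator (not by the
  analysis).
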