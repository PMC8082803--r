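---
title: "Gestational epigenetic age acceleration: models, selection procedure and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gestational epigenetic age acceleration: models, selection procedure and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`gestaar` implements an analysis pipeline for gestational epigenetic age:

1. apply a linear epigenetic clock to CpG beta values to estimate DNA
   methylation gestational age (DNAm GA);
2. summarize clock accuracy (mean and SD of the raw difference to
   chronological GA, median absolute difference, Pearson correlation);
3. compute epigenetic age acceleration residuals (EAAR) by ordinary least
   squares;
4. identify birth- and pregnancy-related correlates of acceleration by
   bootstrapped elastic-net regression with variable-inclusion-probability
   (VIP) stability selection and an elbow rule for model size;
5. replicate findings across cohorts by coefficient transfer and compare
   acceleration across tissues from the same individuals.

Because real perinatal methylation cohorts are rarely shareable, the package
carries a synthetic-cohort generator with planted ground truth. All
statistical claims made by the test suite and by `scripts/acceptance.R` are
claims about recovery of that planted truth.

## Clock application

A clock is a named linear predictor: `age = c0 + sum_j w_j beta_j` over a
fixed CpG set, in weeks or days (days are divided by 7 exactly; no rounding).
Clock CpGs absent from the supplied matrix are, by default, excluded from the
sum without reweighting the remaining coefficients — the practice recommended
by clock authors when arrays lack probes, and the reason estimates from full
and reduced CpG sets stay strongly correlated. A `strict` policy turns any
absent CpG into an error for validation runs. No normalization of betas is
performed or implied; the clock is applied to whatever matrix is supplied.

The accuracy summary reports the *median absolute difference* between DNAm
GA and chronological GA under the name MAD. This is deliberately not the
median absolute deviation from the median: the quantity of interest is how
far estimated age sits from the true age, not the spread of the differences.
SD uses the n−1 denominator throughout.

## Age acceleration residuals

EAAR is the residual of the OLS regression

```
DNAm GA ~ GA + cell-type proportions + ancestry C1 + ancestry C2
```

fit per tissue on complete cases. Positive residuals mean the methylome
looks older than the pregnancy clock says it should (acceleration). The raw
difference `DNAm GA − GA` is easier to read but depends on chronological
age; the residual form removes that dependency and the compositional and
ancestry nuisance structure.

Cell proportions sum to one and are therefore collinear with the intercept;
one proportion must be dropped. We drop the alphabetically last cell-type
name — a deterministic, documented choice. The fitted column space, and
hence the residuals, are identical for any choice of reference (the test
suite asserts this to 1e−8), so the decision is presentational only. A
generalized inverse would give the same residuals; we prefer the full-rank
design because it makes genuine rank deficiency (e.g. duplicated ancestry
columns) an error rather than a silent projection.

For first-trimester chorionic villus samples the regression uses GA at
sampling, not at birth, so that residuals are comparable across
developmental stages; the caller supplies the appropriate GA column.

Residuals are kept in weeks. Standardization to unit variance happens once,
at the entry of the selection stage, never inside `compute_eaar()` — weekly
units are what the cross-tissue means and SDs are reported in.

## Bootstrapped elastic-net selection

The selection engine asks which of 13 birth/pregnancy variables (child sex,
birth weight, birth length, head circumference, maternal age, BMI, smoking,
parity, delivery mode, induced labor, diabetes, hypertensive disorders,
mental disorders; alcohol use can be added as a 14th) predict EAAR. The
procedure:

* z-standardize all predictors and the outcome **once**, on the full
  complete-case data set. Coefficients are then on a common per-SD scale and
  can be aggregated across bootstraps. Re-standardizing inside each
  bootstrap resample would make coefficients incommensurable across
  resamples; this was a genuinely open design point and we chose global
  standardization for exactly that aggregation reason.
* draw `B` bootstrap resamples (n rows with replacement; default 1000, with
  `B = 200` used by the built-in study scenarios, see "Problem sizes"
  below). Per resample, draw one
  10-fold CV assignment and share it across the whole alpha grid, so that
  all mixing parameters compete on identical folds.
* for each alpha in {0, 0.1, …, 1} fit a 100-value lambda path, log-spaced
  from the smallest lambda that zeroes every coefficient down to 1e−4 of it
  (for alpha = 0, whose entry point is infinite, the path is anchored at
  alpha = 0.001, mirroring common elastic-net path construction). The CV
  loss is mean squared error.
* a candidate model's size `nzero` is the count of non-zero coefficients of
  the fit on the **full** bootstrap sample at that (alpha, lambda) — the
  model whose coefficients are actually exported — not of the per-fold fits.
  Within each (bootstrap, nzero) group only the minimum-cvm candidate is
  retained.
* per size, the VIP of a predictor is the percentage of contributing
  bootstraps whose best model of that size includes it; the curve of median
  cvm against size summarizes the bias–variance trade-off.

The solver is a covariance-update coordinate descent for the gaussian
elastic net (penalty `lambda * (alpha*L1 + (1-alpha)/2 * L2)`, unpenalized
intercept, warm starts, active-set iteration; alpha = 0 is solved in closed
form through one eigendecomposition per fit). The test suite cross-checks
coefficient paths against an independent implementation (glmnet) and
verifies our objective value is never higher.

### Choosing the model size

On the curve of median cvm versus nzero we take the interior point farthest
**below** the chord joining the first and last points — the point of most
decreasing error. Both axes are min–max scaled to [0, 1] first: the
farthest-point rule is scale-dependent, and normalizing makes the choice
invariant to the units of the error axis. The distance is signed: the elbow
of a decreasing curve is a point of convexity and lies below the chord,
while points above it mark concavity. This matters in the degenerate case.
The group of size-p models pools by far the most candidates (every ridge
fit plus the small-lambda tail of every alpha), so its per-bootstrap
minimum cvm is the most downward-biased — on an essentially flat curve
(e.g. under a global null) this carves a spurious dip at the right end,
and an unsigned rule would hand the elbow to a near-full model and declare
everything stable. With the signed rule such flat or concave curves simply
have no elbow, and the choice falls back to the smallest interior size
(maximal parsimony, flagged `no_elbow`) — under a null that yields small
models and no stable variables. Ties break to the smallest size. Curves
with fewer than three points or with no net decrease fall back to the size
minimizing median cvm, flagged in the result. Sizes
reached by fewer than 50% of bootstraps are reported but excluded from the
elbow curve; very thinly covered sizes have unstable medians and would
otherwise dominate the geometry. Both the normalization and the 50%
coverage rule were open design points; they are recorded in every output.

### Stability and coefficients

A predictor is *stable* when its VIP at the chosen size strictly exceeds
75% (configurable). Strictness matters at the boundary: a predictor at
exactly 75.0% is not declared stable. Coefficients are summarized per
predictor by the median and the 2.5th/97.5th percentiles (linear
interpolation between order statistics) across the bootstraps in which the
predictor was non-zero at the chosen size. The exported prediction vector
contains the medians of the stable variables and zeros elsewhere.

Note the medians inherit the elastic net's shrinkage: with n = 400 and a
residual SD near 0.8 on the standardized scale, cross-validation-optimal
penalties shrink a planted per-SD effect of ~0.25–0.30 by roughly 0.08–0.12.
The VIP procedure is a selection device, not an unbiased estimator, and the
recovery checks in `scripts/acceptance.R` measure exactly this behaviour.

## Replication and cross-tissue concordance

Coefficient transfer: the stable variables' median coefficients from a
discovery cohort score z-standardized predictors of an external cohort
(standardized within that cohort; no intercept, both sides being
standardized). Replication is the one-tailed Pearson correlation between
predicted and observed EAAR, with `p` from the t transform
`t = r sqrt((n−2)/(1−r²))`, upper tail: the hypothesis is positive
association.

Cross-tissue concordance matches individuals with both tissues (duplicate
tissue samples per individual are an error), reports Pearson correlations
(two-sided p) for DNAm GA and for EAAR, and a paired location test on the
EAAR differences. The parametric/non-parametric gate is concrete:
Shapiro–Wilk on the differences at alpha = 0.05 selects the paired t test
when normality is not rejected and the paired Wilcoxon signed-rank test
(zero differences dropped) otherwise. Both test results are always emitted
so the gate is auditable. Two-sided p-values accompany the cross-tissue
correlations; the replication correlation is the only one-tailed test in
the pipeline.

## The synthetic-data generator

The generator emulates the structure the analysis assumes, with planted
ground truth for every downstream recovery metric:

* **Gestational age**: truncated normal; term tissues mean 40.04, SD 1.55
  weeks on [33, 43]; CVS mean 12.79, SD 0.82 weeks on [10, 15] — the scale
  of term birth cohorts and first-trimester sampling.
* **Predictors**: a latent multivariate normal with a configurable
  correlation matrix; binary variables threshold their latent at the
  quantile matching a realistic prevalence (e.g. smoking 4%, mental
  disorders 11%, delivery mode 30%); continuous variables map affinely to
  realistic means/SDs (e.g. birth weight 3532 ± 489 g). The default
  correlation matrix couples the anthropometric block (weight–length 0.70,
  weight–head 0.60, length–head 0.50), BMI with diabetes (0.25) and
  hypertensive disorders (0.20), and maternal age with parity (0.30).
* **Acceleration**: `a_i = Σ_k γ_k z(X_ik) + ε_i`, ε ~ N(0, σ_a²) with
  σ_a = 0.8 weeks, so that with the planted effects of the
  `cordblood_like` scenario (per-SD effects 0.30, 0.30, 0.25, 0.25, −0.25
  on smoking, birth length, delivery mode, mental disorders and female
  sex) the total acceleration variance is close to one week² and the
  planted standardized effects (~0.25–0.30) clear the 0.2 mark the power
  studies assume.
* **Cell-type confound**: proportions are Dirichlet per tissue; the target
  age receives `δ · z(c_1)` (δ = 0.5 weeks per SD of the first proportion).
  Putting the confound into the *target age* rather than the beta noise
  exercises precisely the adjustment EAAR makes; the tests verify that
  cell-adjusted residuals track planted acceleration better than the raw
  difference does.
* **Betas**: a rank-one construction around a baseline profile
  `m_j ~ U(0.2, 0.8)`: `beta_ij = m_j + v_j (t_i − c0 − w·m) + η_ij` with
  `v = w/(w·w)`, so the embedded clock recovers the target age *exactly*
  when the CpG noise σ_β is zero — clock application is analytically
  testable. The default toy clock (100 CpGs, weights ±1/(0.015·100), i.e.
  0.015 beta units per week along the direction v) keeps noise-free betas
  inside [0.05, 0.95] for gestational-scale deviations; incompatible
  clock/age ranges are an error, and after adding N(0, 0.02²) noise the
  clipped-to-[0,1] fraction is reported (below 1% at defaults, asserted).
* **Cross-tissue coupling**: the acceleration noise vector of an individual
  across tissues is multivariate normal with pairwise correlation ρ. The
  truth object also reports the model-implied correlation between
  *observed* EAARs, which is slightly attenuated below ρ by clock noise
  (variance `Σw² σ_β²`); recovery is assessed against that implied value,
  the correct observable target.

What the generator does **not** emulate: probe-level measurement artefacts,
normalization and batch effects, maternal contamination, genotype structure
beyond two noise ancestry components, non-linear age effects, and real
clocks' CpG lists. Passing recovery tests therefore demonstrate the
statistical machinery under the stated model, not robustness to array
artefacts — those belong to preprocessing, which is out of scope here.

## Problem sizes and numerical choices

The built-in study scenarios use n = 400 cohorts (n = 350 for the
two-tissue design) and 50 seeded replicates of B = 200 bootstraps per
study — sizes chosen so a full acceptance run completes on one CPU in
minutes while keeping VIP granularity at 0.5%. B matters for stability
calls: smaller B widens the Monte-Carlo noise of each VIP estimate around
its true inclusion probability, and variables whose true probability sits
near the 75% threshold then cross it more often — under a global null,
halving B visibly raises the worst-case false-stable rate. The full
B = 1000 of a production analysis is one flag away
(`analysis/04_vip_selection.R --B 1000`).

Coordinate-descent convergence is a maximum coefficient change below 1e−9
per sweep; percentiles interpolate linearly between order statistics;
truncated normals sample by rejection; equicorrelation matrices are checked
for positive semi-definiteness (a 1e−12 jitter stabilizes the Cholesky at
ρ = ±1). All randomness in a run derives from a single integer seed, and
every stage is byte-identical when re-run with the same seed; manifests
record seed, config hash and input checksums.

## Known limitations

* Reported coefficients are shrunken (see above); they order and size
  effects, they do not estimate them unbiasedly.
* The elbow rule needs a curve that actually bends; on flat or monotone
  curves the fallback (argmin of median cvm) is used and flagged.
* Stability percentages at B = 200 have ±3% Monte-Carlo noise near the 75%
  threshold; borderline predictors can flicker across seeds.
* The cross-tissue EAAR correlation is attenuated below the planted
  acceleration coupling by clock noise (the truth object reports the
  model-implied observable value), and its Fisher-z interval runs slightly
  below nominal coverage: residualization consumes degrees of freedom and
  the attenuation factor itself varies between finite cohorts, both
  inflating the sampling spread beyond the textbook `1/sqrt(n - 3)`.
* Complete-case analysis throughout; no imputation.
* One sample per (individual, tissue); repeated measures are not modelled.
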