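---
title: "Multivariate outlier detection as a data quality evaluation process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate outlier detection as a data quality evaluation process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortqc)
```

## The problem

Large observational studies accumulate errors that manual curation and double
entry do not catch: values mistyped into a database, transformed scores
computed from the wrong norm table, processing scripts that miscount events
and silently distort every measure derived from the count. Some of these
errors produce values that are extreme on a single variable and are caught by
any univariate screen. The more insidious ones produce values that are
*individually* unremarkable but jointly impossible — a transformed score far
off the regression band of its own raw score, or a walk whose per-step
averages disagree with its step count. Only multivariate detection, which
models the joint covariance of the measurements, can surface these.

`cohortqc` implements a data quality evaluation loop built around two
complementary multivariate detectors — a fast minimum covariance determinant
(MCD) pipeline and a sparsity-targeted robust principal component analysis
(RPCA) pipeline — plus univariate comparators, cross-method compilation of a
verification list, and ground-truth benchmarking on synthetic cohorts.
Detection is run four ways (each detector, with and without covariate
adjustment); participants flagged by at least two of the four runs form the
list handed to the data-collecting team for verification against source
documents. Confirmed errors are corrected and the whole process repeats until
no corrections occur and the list is static. Iterating matters: correcting a
gross error can unmask a second, subtler error in the same participant that
the first had dominated.

## Preparation

Each variable is optionally residualized on age, a binary sex indicator, and
years of education using the full factorial model (intercept, three main
effects, all interactions — eight design columns), fitted per variable on the
rows where that variable is observed. Residualization removes expected
demographic gradients so the detectors respond to deviations from the
cohort's covariance pattern rather than to normal aging. Missing entries are
then mean-imputed, and every column is scaled to zero mean and unit sample
standard deviation (computed on observed values only). An imputed cell is
therefore exactly 0 after preparation and cannot by itself drive a flag.

The order — adjust on observed values, then impute, then standardize — keeps
the imputation constant out of the regression slopes. Constant columns are
centered, given scale 1, flagged with a warning, retained for univariate
summaries, and dropped from the multivariate estimators (they make the
covariance singular).

## The MCD pipeline

The MCD estimates a robust mean and covariance from the `h`-observation
subset whose covariance determinant is minimal. The subset size is set by the
robustness parameter `alpha` through

```
h = floor( 2*floor((n+p+1)/2) - n + 2*alpha*(n - floor((n+p+1)/2)) )
```

so `alpha = 0.5` gives the most robust subset `floor((n+p+1)/2)` and
`alpha = 1` keeps everything. The exact minimum is combinatorial, so
`fast_mcd()` uses the concentration search: random `(p+1)`-subsets are
improved with C-steps (recompute distances from the current subset's
mean/covariance, keep the `h` closest — provably non-increasing in the
determinant), the most promising candidates are iterated to their fixed
points, and the best fixed point wins. The subset covariance uses the
maximum-likelihood (`1/h`) divisor and is multiplied by the consistency
factor `c0 = (h/n) / P(chi2_{p+2} <= qchisq(h/n, p))`, which corrects the
downward bias of estimating a covariance from the most concentrated fraction
of a normal sample; no additional finite-sample correction is applied.

Robust Mahalanobis distances are mapped to `[0, 1)` by
`r = 1 - 1/(1 + m)`, and the flagging threshold is calibrated by simulation:
100 multivariate normal samples of size `n` are drawn from the robust
estimates, every simulated observation's outlyingness is computed against
those same estimates, all `100 * n` values are pooled, and the `eps_mcd`
empirical percentile of the pool is the threshold. Pooling (rather than
averaging per-sample percentiles) uses all simulated values in one empirical
distribution and is the default; the per-sample alternative is available via
`pool = FALSE`. With `eps_mcd = 0.99` about 1% of clean observations exceed
the threshold by construction, which is what the null-calibration tests
verify.

Because a Mahalanobis distance says nothing about *which* variables are
responsible, each observation's squared distance is partitioned into `p`
per-variable terms by the corr-max transformation: with
`D = diag(1/sqrt(diag(Sigma)))`, the matrix `C = (D Sigma D)^{-1/2} D`
(symmetric square root via eigendecomposition) gives contributions
`w_i = C (x_i - mu)` with `sum_j w_ij^2 = m_i^2` exactly. Among orthogonal
partitions this choice maximizes the correlation between each variable and
its own contribution column, so ranking `|w_ij|` names the variables to
check first.

## The RPCA pipeline

The second detector decomposes the prepared matrix as `X = L + S` with `L`
low-rank and `S` sparse, by principal component pursuit:
`min ||L||_* + lambda ||S||_1` subject to `X = L + S`. The solver is the
inexact augmented-Lagrangian iteration — alternate singular-value
soft-thresholding (the proximal step for the nuclear norm, updating `L`)
with elementwise soft-thresholding of the residual (updating `S`), plus a
dual update that drives the reconstruction gap to zero. Iterations stop when
the max-entry gap falls below `1e-7 * ||X||_F` (cap 500 iterations per
lambda).

On real, noisy study data the conventional starting weight
`lambda0 = 1/sqrt(max(n, p))` usually leaves far more of `X` in `S` than is
useful for naming contributing variables. The pipeline therefore takes a
sparsity target `tau` (default 0.05): whenever the returned `S` has a
nonzero fraction of at least `tau`, the l1 weight is strengthened by the
factor `1/decay` (default `decay = 0.9`, about an 11% increase per outer
loop) and the decomposition is rerun; the first decomposition below the
target is returned. Strengthening the weight is the direction that
monotonically empties `S` in this objective, so the loop always terminates —
a decomposition that is already sparse enough at `lambda0` is returned
immediately.

Outlyingness is measured per participant by orthogonal distances:
`o_xs = sum_j (x_j - s_j)^2` and `o_ls = sum_j (l_j - s_j)^2`. For a
participant fully explained by the low-rank structure, `x = l` and the ratio
`o_ls / o_xs` is 1; sparse entries absorbing real deviation pull it away
from 1. The deviations `|ratio - 1|` are ordered and the `eps_rpca`
percentile (type-7 empirical quantile, inclusive at the threshold so the
flag count is deterministic) separates the flagged tail. Both tails of the
ratio are catchable this way, and the reciprocal orientation
(`o_xs / o_ls`) is available as a configuration switch since either
direction of the proportion is a defensible deviation measure. A flagged
participant's nonzero `S` entries, ranked by absolute magnitude, are its
contributing variables.

## Univariate comparators

Two per-variable screens quantify what a variable-at-a-time process would
have caught. The univariate MCD is exact rather than randomized: the
minimum-variance `h`-subset of a univariate sample is contiguous in sort
order, so a scan over the `n - h + 1` sorted windows finds it (the test
suite verifies the contiguity claim against brute-force enumeration of all
`h`-subsets at small `n`). The robust mean and `c0`-corrected variance feed
the same outlyingness transform and the same pooled simulation threshold as
the multivariate pipeline, with a 1-by-1 covariance — which makes the
univariate detector the *exact* `p = 1` reduction of the multivariate one
given a shared seed, a property the suite asserts. A variable whose
concentrated subset has zero variance (e.g. 139 identical values among 161)
is excluded with an explicit reason, since no distance can be formed.

The boxplot screen flags values strictly beyond the Tukey fences
`Q1 - 1.5*IQR` and `Q3 + 1.5*IQR`. Quartiles use linear interpolation of
order statistics (type-7, R's default); the convention is recorded in the
output because fence positions depend on it and figures alone cannot
disambiguate which convention another implementation used.

## Compilation and iteration

`compile_outlier_list()` combines the four multivariate runs. A participant
is listed when flagged by at least `min_flags = 2` of the four — frequency
of detection is read as generality of deviance, while keeping the rule at
two (not three) retains errors that only one method family sees.
Contributions are merged by interleaving each method's own ranking (all
rank-1 picks first), ties at a rank broken by absolute value, with
per-method provenance preserved.

`run_iteration()` wraps one pass: apply externally verified corrections
(the tool never auto-corrects — classification of a flagged value as
erroneous versus atypical-but-correct is a human verification step),
re-prepare, re-detect, re-compile. Convergence requires that no correction
was applied and the listed set matches the previous pass. By default every
iteration reuses the same derived simulation seed: on unchanged data the
detectors then return identical flags, so the convergence check compares
datasets rather than Monte-Carlo noise. Redrawing seeds each pass is
available (`reseed_each_iteration = TRUE`) but makes "static" a statistical
rather than exact statement.

`parameter_sweep()` reruns detection over grids of `alpha` and `eps_rpca`
and tabulates flag counts and overlaps, which is how the verification burden
of a threshold choice is assessed before committing a team to checking the
list.

## The synthetic cohort generator

Because real cohort data of this kind are not redistributable, the package
ships a generator that emulates their statistical structure, with defaults
fixed once to a realistic desk-scale cohort:

* demographics matching a vascular-cohort profile: age normal with observed
  mean 68.72 and sd 7.42 truncated to [55, 85], education with observed
  mean 14.61 and sd 2.92 truncated at 6 years, sex Bernoulli(110/161).
  Truncation shrinks a normal's spread, so the generator inflates the parent
  sd (closed-form truncated-normal moments, solved numerically) to make the
  *observed* moments match the targets;
* 8 raw/transformed score pairs with within-pair correlation 0.9 — the
  transformed member is a monotone linear map of its raw member plus noise
  calibrated to the target correlation — on a raw-score scale
  (mean 30, sd 5);
* 2 blocks of 6 mutually correlated task variables (within-block correlation
  0.8 via a shared latent factor) on a per-walk gait-summary scale
  (mean 60, sd 3, i.e. a ~5% coefficient of variation);
* covariate effects of −0.03 per year of age, +0.4 for sex, +0.05 per year
  of education, in standardized-variable units, applied to every variable.
  Neither block correlation nor effect sizes are published quantities; these
  values were chosen once as typical of cognitive and gait measures and are
  fully overridable.

Three error mechanisms are injected with a ground-truth log. Transcription
errors replace a cell with another participant's value. Transform
miscalculations shift the transformed member of a pair so that the cell
stays inside its own variable's boxplot fences (fences recomputed on the
corrupted column, with a 3% margin, so a later univariate screen cannot flag
it) while its pair residual exceeds ~6 residual standard deviations —
exactly the geometry that motivates multivariate detection. Block miscounts
rescale one block by `(s ± 1)/s` for a plausible step count `s` (12–24):
half the block's variables are treated as count-proportional and half as
count-inverse, since derived task measures depend on an event count in both
directions, and it is this broken within-block relationship (not the small
marginal shift) that makes a miscount detectable.

What the generator does *not* emulate: bounded and discrete score supports,
floor/ceiling effects, skewness, missingness mechanisms beyond
missing-completely-at-random, and platform-specific artefacts. The
detectors operate on standardized values under an implicitly Gaussian
working model (the thresholds are calibrated on multivariate normal
simulations), so passing tests demonstrate correct behaviour under that
model — they do not certify performance on heavily non-Gaussian real data.

## Numerical choices

* Matrix inverse square roots use the symmetric eigendecomposition branch;
  Mahalanobis distances go through the Cholesky factor, never an explicit
  inverse; singular or non-positive-definite scatter raises an error naming
  near-collinear pairs where identifiable.
* Ties in "h smallest distances" are broken by row order, making the search
  deterministic given its seed.
* All percentile rules use type-7 quantiles; RPCA flags are inclusive at the
  threshold.
* The fast-MCD default is 500 random starts (cap 100,000), two C-steps per
  start, and full iteration of the 10 best candidates — the standard
  trade-off between search quality and cost; the exhaustive-oracle tests
  confirm the global minimum is found at small `n`.
* RPCA tolerance is `1e-7 * ||X||_F` with 500 inner iterations per lambda
  and at most 200 outer lambda steps.
* Degenerate inputs: constant columns are excluded from covariance-based
  estimation with a warning; fully-missing columns, rank-deficient covariate
  designs and `n <= p` raise informative errors (the MCD is undefined for
  `n <= p`; wide data should use the RPCA pipeline only).

## Problem sizes in the test suite

The suite exercises the estimators at sizes chosen to keep a full run in a
few minutes while retaining power: exhaustive-oracle comparisons at
`n = 12, p = 2` (792 subsets), 1000-draw invariant checks, null calibration
at `n = 200, p = 10` over 50 seeds, RPCA contracts over 50 constructed
`n = 100, p = 20` instances, and the error-sensitivity benchmark over 20
synthetic cohorts of `n = 200` with 5 injected pair-breaking errors each.
The acceptance script (`scripts/acceptance.R`) recomputes the same
quantities from scratch at comparable sizes.

## Limitations

The MCD requires `n > p` and both detectors require continuous variables;
categorical and mixed-type data are out of scope, as are `n < p` MCD
variants, multiple imputation, robust (median/MAD) scaling, and
skewness-adjusted boxplots. Errors that do not deviate from the cohort's
joint pattern — and systematic errors shared by many observations — are
invisible to any detector of this kind; outlier lists are nominations for
human verification, not verdicts.
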