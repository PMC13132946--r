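---
title: "Twin ACE models in twinace: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin ACE models in twinace: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinace)
```

## The model

The classical twin design decomposes phenotypic variance into additive
genetic (A), shared environmental (C) and unshared environmental (E)
components by contrasting monozygotic (MZ) pairs, who share all segregating
genes, with dizygotic (DZ) pairs, who share half on average. For `p` traits
the stacked 2p-vector of a pair's phenotypes is modelled as multivariate
normal with

* within-twin covariance blocks `A + C + E`,
* cross-twin block `A + C` for MZ and `0.5 A + C` for DZ pairs,

where A, C, E are p×p symmetric matrices. The ADE variant replaces C by a
dominance matrix D (cross-twin weight 1 for MZ, 0.25 for DZ); C and D are not
jointly identifiable in a design with reared-together twins only, so the
choice between ACE and ADE follows the intraclass-correlation rule
implemented in `select_model_family()`: ACE when `r_MZ <= 2 r_DZ`, ADE
otherwise (exact equality is a documented tie-break to ACE). Means are linear
in covariates — by default age and sex, optionally years of music training —
with identical coefficients for both members of a pair (twin order is treated
as exchangeable in structured models; the assumption ladder tests exactly
this kind of assumption).

Key assumptions inherited from the design: multivariate normality of the
phenotypes, equal environments across zygosities, no assortative mating, no
gene–environment correlation or interaction, and linear covariate effects.
None of these are testable inside the package beyond the equality ladder.

### Direct symmetric parameterisation

Every unique element of each component matrix is a free parameter; there is
no Cholesky factorisation and no bound forcing components to be positive
semidefinite. This is deliberate: boundary behaviour in which a component
correlation (e.g. the shared-environment correlation between two
self-evaluation measures) is estimated above 1, or a component variance
slightly below 0, is only expressible in this parameterisation. Such values
are reported verbatim with a `boundary` flag; display columns cap
correlations at ±1 and a component correlation whose variance is negative is
reported as `NA` (undefined) rather than invented. The only global
requirement is that the *total* implied pair covariance be positive-definite
wherever the likelihood is evaluated; parameter points violating this return
a large penalized objective value, sloped by the most negative eigenvalue so
the optimizer is pushed back toward the feasible region instead of stalling
on a plateau.

## The likelihood

`minus_two_loglik()` is full-information maximum likelihood: every family
contributes the multivariate-normal density of its *observed* values, with
the rows/columns of the expected mean and covariance for missing entries
deleted. Singletons therefore contribute marginal densities and help pin
down means and variances; no imputation is performed. The production path
groups families by (zygosity × missingness pattern) and uses one Cholesky
factorisation per group; the test suite checks it to 1e-10 against an
independent per-family evaluation using `det()` and `solve()`.

Degrees of freedom follow the observed-data convention: `df` equals the
number of non-missing modelled values minus the number of estimated
parameters (EP), and `AIC = -2LL + 2 EP`.

### Parameter counting

EP counts unique free parameter classes: equality-constrained parameters
count once and derived parameters (see below) count zero. For the trivariate
correlated-factors ACE model with intercept, age and sex per trait this
gives 18 component + 9 mean = 27 parameters. Published tables for this model
class sometimes report 30 for the same model; the extra three cannot be
reconstructed from a mean model with one intercept and two covariate slopes
per trait, so the package reports its own transparent count. Differences
between nested models — the quantities entering every likelihood-ratio test
— are unaffected (dropping C removes 6, fixing the three C correlations
removes 3, equating two C variances removes 1).

### Constraints

All submodels are generated by four verbs on a `twin_model_spec`:

* `drop_component()` — fix an entire matrix to 0 (AE/CE/E submodels);
* `drop_component_for()` — fix one trait's variance and covariances in one
  component to 0 (per-variable drop-C tests);
* `fix_component_correlation()` — replace each off-diagonal element by the
  derived quantity `rho * sqrt(X_ii X_jj)`, bounding those diagonals at 0
  (the derived covariance is undefined for negative variances);
* `equate_params()` — merge parameters into one equality class (refusing to
  merge across different matrices, where equality has no meaning).

## Optimization

`fit_twin_model()` minimizes the deviance with `stats::nlminb` (box
constraints where a constraint demands them), objective tolerance 1e-8.
Starting values come from sample moments: per-group means/variances/
covariances for saturated models (clamped into the feasible cone, since two
observed pairs always produce a sample correlation of ±1), and an equal
split of the pooled sample covariance across A, C and E plus per-trait
least-squares mean coefficients for structured models. By default two
additional restarts jitter the start by 0.1× the parameter scale under a
user-supplied seed; the best converged solution is kept, so results are
deterministic given data and seed. Non-convergence is flagged, never
silently returned. An optional central-difference gradient-norm check
(`grad_check`) verifies solutions at a cost of 2·EP extra evaluations.

## Confidence intervals

`profile_ci()` and `profile_share_ci()` are profile-likelihood intervals:
a bound is the parameter value at which the deviance, re-minimized over all
other parameters, exceeds the minimum by the χ²(1) quantile (3.841 at 95%).
Standardized shares are profiled by *constrained refitting*: at trial share
s, the component's variance for that trait is derived from the other
components so it accounts for exactly s of the total. When the lower profile
of a positive share reaches the natural boundary 0 the bound is reported as
exactly 0 with a boundary flag — matching the reporting convention for
non-significant shared-environment shares. A bound that cannot be bracketed
is flagged, not guessed. Intervals for the twin correlations profile the
correlation parameter of the constrained bivariate (ICC) or quadrivariate
(CTCT) normal model. Profile intervals are the package default for this
model class; significance tiers for shares are defined by whether the 95%,
99% and 99.9% profiles exclude zero.

## The assumption ladder

`run_assumption_ladder()` fits a per-trait saturated model over the
zygosity-by-pair-sex subgroups (MZ female, MZ male, DZ female, DZ male, DZ
opposite-sex), then a fixed cumulative sequence of equality constraints:
means across twin order → zygosity → sex; variances in the same order;
within-pair covariances across sexes, then across zygosities. Each rung is
compared to the previous by likelihood-ratio test at α = 0.01.

Two design choices were genuinely open:

* The final rung (covariances across zygosities) is computed but excluded
  from pass/fail by default. Equating MZ and DZ within-pair covariances is a
  test of equal familial aggregation, which *must* fail whenever genetic
  effects are present; treating it as an assumption check would contradict a
  nonzero heritability. A flag restores it to pass/fail for users who want
  the strict reading.
* Opposite-sex DZ pairs form their own subgroup for mean/variance rungs and
  are excluded from the sex-equality covariance rung (their within-pair
  covariance mixes sexes). Subgroups with fewer than three complete pairs
  are excluded entirely, with an explicit note — below that size the
  subgroup's saturated covariance is degenerate.

Under the null the rung p-values are uniform; the test suite checks this by
Kolmogorov–Smirnov over 500 simulated replicates.

## Twin correlations

`intraclass_correlation()` is the ML correlation of a constrained bivariate
normal (means and variances equated across twin order, covariate-adjusted
means), which pools both twin orders symmetrically; `ctct_correlation()` is
the analogous quadrivariate ML fit in which the two cross-twin cross-trait
covariances are equated. The constrained-ML route matches the modelling
framework used everywhere else in the package; a double-entry Pearson
estimate is available (`method = "double_entry"`) as a diagnostic
cross-check and agrees closely in practice.

## The simulator

`simulate_twin_data()` draws each pair's 2p phenotype vector directly from
the model-implied pair covariance (so generative fidelity is exact by
construction), adds the linear mean model, and emits the package's standard
one-row-per-twin table. `twin_sim_preset()` encodes the study conditions the
package is built around: 335 MZ complete pairs (252 female-female, 83
male-male), 118 DZ pairs (85 female-female, 26 male-male, 7 opposite-sex of
the 118), 90 singletons, age normal(45.70, 16.27²) truncated to [15, 90] and
shared within pair, training years exponential with mean 4.55 winsorized at
20 (the published moments give mean ≈ SD ≈ 5, which the exponential matches
with one parameter), and a trivariate generating structure whose
standardized diagonals are the published univariate estimates and whose
cross-matrices are assembled from the published component correlations. The
shared-environment correlations were estimated at or above 1; a generating
covariance cannot use such values, so the preset caps them at 0.95 — the
largest round value that keeps the generating C matrix proper. Covariate
slopes default to zero, consistent with the null assumption tests the study
reported; tests that exercise covariate machinery set nonzero slopes
explicitly.

What the simulator does *not* emulate: gene–environment correlation or
interaction, assortative mating, sex-limitation (component differences by
sex), age–variance interactions, non-normal phenotype distributions, and —
by default — the discreteness of the 1–7 single item. The 7-point item is
generated continuously because the modelling treats it as continuous; a
Likert mode (six thresholds at normal septiles) exists to study coarsening
bias. Consequently, passing recovery tests demonstrate correctness of the
estimator under the stated generative model, not robustness to these
real-data features.

## Problem sizes and numerical choices

Recovery checks refit at 10,000 pairs per zygosity, where the Monte-Carlo
standard deviation of a standardized share is ≈ 1.4 percentage points;
calibration and uniformity checks use 500 replicates at a few hundred pairs,
sizes chosen to make Monte-Carlo error small relative to the tolerances
while keeping the full suite fast on one CPU. Degenerate inputs are handled
explicitly: all-missing families are dropped and counted; zero total
variance, non-nested comparisons, and fits that would silently fail all
raise errors; ties in the ACE/ADE rule go to ACE; p-values are displayed to
3 decimals but compared unrounded.

## Known limitations

* No ordinal (threshold/probit) likelihood — the 7-point item is modelled as
  continuous, as in the analysis the package reproduces.
* No sex-limitation, gene–environment interplay, common-pathway or
  independent-pathway models.
* No robust standard errors or Bayesian estimation.
* Saturated ladder models are univariate per trait; cross-trait assumption
  tests are out of scope.
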