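---
title: "Biometric twin models in twinpath: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biometric twin models in twinpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinpath)
```

## The models

`twinpath` fits biometric variance-decomposition models to same-sex MZ/DZ
twin-pair phenotype tables. All three families share one algebraic frame:
each variance component X in {A, C, E} is written as a Gram matrix
X = L_X L_X', where L_X is a p x m matrix of factor loadings whose free/zero
pattern defines the model. The within-twin covariance is
V = A + C + E; the cross-twin block is A + C for MZ pairs and 0.5 A + C for
DZ pairs, because MZ twins share all and DZ twins on average half of their
segregating genes, while non-shared environment never crosses twins. The
2p x 2p pair covariance is assembled from these blocks per zygosity (and
sex, under sex limitation).

* **Univariate ACE** (`univariateACE()`): p = 1, one loading per component
  (the familiar a, c, e paths).
* **Cholesky** (`choleskySpec()`): loadings are lower-triangular over
  occasions, so factor k describes variance first arising at occasion k and
  its persistence afterwards. Heritability at occasion k is the sum of the
  standardised genetic contributions of factors 1..k
  (`choleskyAccounting()`).
* **Independent pathway** (`ipmSpec()`): per component, a common factor
  loading on all p variables (C1), an optional second common factor
  restricted to the later-occasion variables (C2), and p specific factors.
  The split of each variable's h2/c2/e2 across C1/C2/S is the
  common/specific table (`commonSpecificTable()`); cross-trait
  correlations decompose into A/C/E shares by path tracing
  (`correlationShares()`).

Parameterising through loadings keeps every component contribution positive
semi-definite for any real parameter value, so the optimiser needs no
inequality constraints; the cost is a sign indeterminacy per factor, which
is resolved after fitting by forcing each factor's first non-zero loading
non-negative.

### Sex limitation

Two forms are supported, matching standard practice. *Scalar* limitation
multiplies all of a variable's loadings by one free constant in female
pairs: phenotypic variance differs by sex while standardised proportions
are sex-invariant (the scalar cancels; this is asserted in the test suite,
not assumed). *Quantitative* limitation frees separate male and female
loadings for designated variables. Either switches estimation from two
groups (MZ, DZ) to four (MZ/DZ x M/F); with same-sex pairs only, that
four-group likelihood is what identifies the models.
`testSexDifferences()` runs the standard nested ladder
(none, scalar, quantitative) for one trait and reports both chi-square
comparisons.

## Preprocessing

Raw phenotypes are regressed on sex (pooling twins; with a single binary
covariate this is removal of per-sex means, so pair clustering cannot bias
the point estimates) and then rank-based inverse-normal transformed: Blom
scores, qnorm((rank - 3/8)/(n + 1/4)), ties to average ranks, pooled across
twins within a variable so twin labelling is irrelevant, then standardised
to exact mean 0 and variance 1. The transform family for "normalisation"
was a genuinely open choice; rank-based inverse-normal was picked because
it is reproducible, monotone and maps any continuous marginal to
near-normality, which is what the Gaussian likelihood downstream assumes.
Missingness is never imputed: both steps leave missing cells missing, and
the missing-cell count is invariant (tested).

Because the likelihood operates on residualised, standardised data, the
mean vector is fixed at zero rather than estimated. Freeing the means (as
general-purpose SEM software would) adds nuisance parameters that are
exactly zero in expectation here; fixing them is declared and covered by
the recovery tests.

## Estimation

The objective is raw-data (full-information) maximum likelihood: each
pair contributes the multivariate-normal -2 log-density of its observed
sub-vector under its group's implied covariance. Internally, pairs are
grouped by zygosity(-sex) and missingness pattern, and each pattern's
cross-product matrix is precomputed once; an objective evaluation then
costs one Cholesky factorisation per pattern instead of one per pair,
which is what makes the 60-parameter IPM fit on 10,000 pairs tractable in
seconds. The test suite verifies this machinery against a dense per-pair
oracle (direct determinant/solve evaluation) to 1e-8, including under
missingness.

Optimisation runs in three stages:

1. **Quasi-Newton descent** (`nlminb`, PORT) from a deterministic
   moment-informed start — each variable's Falconer decomposition
   (h2 = 2(rMZ - rDZ), etc., clipped away from the boundary) spread evenly
   over that component's free loadings — plus seeded, perturbed restarts
   (default 5).
2. **Sharpening** by BFGS with central-difference gradients at tight
   tolerance. nlminb's internal forward differences locate the optimum
   only to ~1e-4 on an objective of magnitude ~1e5, which is not precise
   enough for chi-square difference tests between separately fitted nested
   models; the sharpened optima agree at ~1e-9.
3. **Boundary snapping**: the likelihood is quartic-flat in any loading
   near zero (it enters only through its square), and on a curved ridge
   zeroing one coordinate only pays off after the others adjust. Small
   coordinates are therefore trial-set to exactly zero and the rest
   re-polished; the candidate is kept only when the objective strictly
   improves. This makes boundary solutions (e.g. a true C = 0) exact
   rather than wobbling at |c| ~ 0.01.

A non-positive-definite implied covariance during search yields a large
finite sentinel value (1e10), not an exception, so line searches can back
off. Convergence tolerances default to 1e-8 (objective) and 1e-6
(parameters); `FitResult`s record seeds, per-start diagnostics and group
sizes, and refitting from a returned optimum moves the objective by less
than 1e-6 (tested).

Confidence intervals are delta-method intervals from the inverse observed
information (numerical Hessian of the -2 log-likelihood; its inverse times
2 is the parameter covariance), reported on both the path scale and the
standardised variance-contribution scale. The contribution scale is what
the pruning rule uses.

### Nested tests and pruning

`twinLRT()` reports the naive upper-tail chi-square probability of
delta(-2LL) at delta(df), with delta(df) = 0 giving p = 1 by convention.
For variance components tested on the boundary the naive reference is
conservative (the 1/2-chi-square mixture issue); the naive value is what
is reported, with a note attached, because that is the convention in the
applied literature this package serves, and the type-I simulation in the
test suite confirms the conservatism. `pruneSmallPaths()` iteratively
fixes to zero the smallest standardised contribution below 0.05 whose 95%
interval covers zero, refitting between constraints; paths whose removal
would leave a variable with zero E variance are exempt, sex scalars are
never pruned, and for sex-specific paths both sexes must qualify.

## The synthetic-cohort generator

`simulateTwins()` draws each pair's 2p-vector from the zero-mean Gaussian
with the group's implied covariance and applies
missing-completely-at-random masking; data are generated on the
standardised scale, i.e. already "normalised". The default cohort mimics
the emulated study's scale: 1,116 same-sex pairs, 56% MZ, 49% male, no
missingness. `referenceIPMComponents()` carries the published standardised
component table for the 8 isolation/mental-health variables (ages 12 and
18, male conduct column canonical, the female conduct-12 row kept
alongside), and `ipmTruthFromComponents()` converts it to generating
loadings via loading = sqrt(total x percentage/100). Printed rows are
rounded (totals sum to 100.01, splits to 100.01), so by default the
converter rescales totals to sum exactly to 1 and splits to exactly 100;
round-tripping `standardiseFit()` over the exact parameters then
reproduces the normalised inputs to machine precision and the printed
rows to within 0.05 of a percentage point.

What the generator deliberately does not emulate: rater and instrument
effects, ordinal item scales and threshold liabilities, selective
attrition (masking is MCAR only), age heterogeneity within wave, and
opposite-sex pairs (the emulated cohort has none). Passing recovery tests
therefore demonstrate correctness of the estimator under the model's own
assumptions, not robustness to these real-data features.

## Problem sizes and stochastic checks

Simulation-based tests in the suite run at the sizes where their
tolerances are meaningful: intraclass-correlation checks at 10,000 pairs
per zygosity (+/-0.03), Falconer-vs-FIML triangulation at 10,000 per
zygosity (+/-0.05), parameter-recovery means over 10 replicates of
5,000 + 5,000 pairs, type-I error of the ACE-vs-AE test over 30 null
replicates of 2,000 + 2,000, pruning behaviour over 25 replicates, and the
IPM recovery demonstration as a single 5,000 + 5,000 cohort fit. At that
cohort size the sampling SD of a recovered heritability is roughly 2
percentage points (measured across seeds during development), so
single-draw recovery bands of +/-3 points operate at about 1.5 SD — an
individual draw can land outside them while the estimator remains
unbiased; the recovery tests on means are the stronger bias check.

## Numerical choices and degenerate inputs

* Implied covariances are symmetrised against floating-point drift;
  symmetry, block equality and the MZ/DZ cross-block arithmetic are
  property-tested on random parameter draws.
* A variable observed in only one sex still residualises (per-sex mean
  removal stays defined); an all-missing or constant variable is an error;
  fewer than 10 observed values warns.
* Double-entry ICCs need at least 3 complete pairs per zygosity; empty
  descriptive cells are reported as missing rather than dropped.
* Components with zero totals produce undefined (NA) percentage splits,
  never NaN propagation; a zero implied correlation flags its shares
  undefined.
* Pairs with all variables missing are dropped with a logged count before
  fitting; a variable with no observations in one zygosity group blocks
  fitting with a clear error.
* YAML/JSON serialisation covers specs, fits and reports; CSV output
  prints 17 significant digits so write/read round trips are bit-exact.

## Known limitations

Dominance (ADE) and common-pathway/rater models, ordinal threshold
liabilities, opposite-sex pairs, profile-likelihood intervals (an
observed-information default is used; the profile route is the natural
extension), and robust/sandwich standard errors are out of scope. The
boundary non-regularity of variance-component tests is acknowledged but
not corrected beyond the conservative naive p-value. Quantitative sex
limitation prunes structurally (both sexes together), not per sex path.
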