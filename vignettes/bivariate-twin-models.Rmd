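---
title: "Bivariate variance-component twin models in bivtwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bivariate variance-component twin models in bivtwin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivtwin)
```

## The model and its assumptions

`bivtwin` implements the classical twin design for two continuous traits
measured on same-sex monozygotic (MZ) and dizygotic (DZ) twin pairs, in
four groups (MZf, DZf, MZm, DZm). The pair vector — twin 1's two traits
followed by twin 2's — is assumed multivariate normal within each group,
with mean `(mu, mu)` (twins are interchangeable in expectation) and a
block covariance

$$\Sigma \;=\; \begin{pmatrix} W & X \\ X & W \end{pmatrix},
\qquad W = A + C + E, \qquad X = a\,A + c\,C,$$

where $A$, $C$ (or $D$), $E$ are 2×2 symmetric component covariance
matrices. MZ twins share all segregating genes ($a = 1$), DZ twins half
on average ($a = 0.5$); the shared-environment component is common to
both twins in both zygosities ($c = 1$), while a dominance component is
shared fully by MZ and one quarter by DZ pairs ($c = 0.25$). $C$ and $D$
are not jointly identified with twins reared together, so one model
family (ACE or ADE) is chosen from the pattern of twin correlations:
dominance is indicated for a trait when $r_{MZ} > 2 r_{DZ}$.

Key assumptions inherited from the design: normality of the (sum-score)
phenotypes, which are treated as continuous; no assortative mating,
gene–environment interaction or correlation; equal environments across
zygosities; and missingness at random, under which the full-information
likelihood below is valid.

The two sexes may disagree on the family heuristic. A single bivariate
model still needs one family, so the ladder uses ADE when the criterion
fires for *any* sex–trait combination (the `"any"` rule, configurable to
`"all"`). The practical consequence is small: when the data carry no
dominance signal, the D component is dropped at the first ladder step and
the retained model is the same AE model either way. Exact ties
($r_{MZ} = 2 r_{DZ}$) go to ACE.

## Likelihood and missing data

Each pair contributes the density of its *observed* sub-vector
(full-information maximum likelihood), so incomplete pairs are retained
without imputation. Internally the dataset is compressed once into
per-group, per-missingness-pattern sufficient statistics (count, mean,
maximum-likelihood scatter); every deviance evaluation is then a sum of
at most 15 closed-form terms per group, independent of the number of
pairs. With no missing data this reduces exactly to the closed-form
complete-data multivariate-normal deviance, which the test suite checks
against an independent row-by-row oracle to 1e-8 relative accuracy.

## Parameterization and numerical choices

Component matrices are estimated **directly** (the variance-component
approach) rather than through Cholesky factors: entries are free reals,
components may be indefinite, and only the implied total covariance of
each group must be positive definite — the evaluator returns an
effectively infinite deviance (1e10) elsewhere. This avoids the boundary
bias that Cholesky parameterizations induce in likelihood-ratio tests of
variance components. A corollary is that genetic or environmental
correlations can exceed 1 in magnitude when a component estimate is
indefinite; they are reported with a warning, not truncated, so the
indefiniteness stays visible.

Optimization uses the PORT quasi-Newton routines (`nlminb`) with analytic
gradients of the FIML deviance (assembled per missingness pattern and
chained through the component structure) for the sex-specific and
sex-equated modes; the scalar mode uses numerical gradients. Starting
values are data-driven — means from group averages, each present
component initialized to an equal share of the pooled within-twin
covariance — plus two or three deterministically jittered restarts drawn
from a fixed jitter seed that is insulated from the caller's random
stream, so simulation loops remain reproducible. Along a model ladder
each nested fit is warm-started from its base (and the base refitted from
the nested optimum if the optimizer ever leaves it above the nested
model), which enforces the monotone nesting of −2LL up to 1e-6.

The saturated model optimizes a log-Cholesky parameterization per group
(by default with means and covariance blocks equated across twin order,
which makes the descriptive twin correlations well defined); with
complete data and no constraints it short-circuits to the closed-form ML
solution. The saturated constraints are a package choice — standard twin
practice — since reasonable alternatives (fully unconstrained; order
pooling at the correlation stage only) are also supported via the
`constraints` argument and `pool_twin_order` flag.

Means are sex-specific and equated across twin order and zygosity in
every biometric model, including the "no sex differences" model, which
equates only the component matrices (the sexes differ in means in most
phenotypes, and mean structure is not what the variance-component tests
are about). Degrees of freedom follow the convention
`df = observed data points − free parameters`, and
`AIC = −2LL − 2·df`: this is the arithmetic used in the published tables
this package mirrors, and differs from the common `−2LL + 2·(free
parameters)` only by a per-dataset constant, so model orderings agree.

Likelihood-ratio tests of components at their boundary (e.g. C = 0) are
referred to the naive $\chi^2$ distribution, matching field practice;
this is conservative (the type-I rate is at or below nominal), which the
suite verifies by simulation. Sex-difference tests of the component
matrices drop 2 × 3 = 6 parameters at once; the default threshold for the
genetic-model ladder is $\alpha = 0.01$.

### Scalar sex limitation

The scalar model constrains the standardized architecture to be equal
across sexes while letting total variances differ: male components are
free and female components are obtained by scaling trait $t$'s rows and
columns by $\sqrt{k_t}$, so female total variance is $k_t$ times the male
total variance and every variance share, covariance share and component
correlation is identical across sexes. With sex-specific means this model
has 12 free parameters in the AE case, against 16 for the unconstrained
AE model — a 4-df test. (Published applications sometimes report this
comparison with other df, depending on whether means and a single common
$k$ are constrained; the parameterization here is one $k$ per trait,
means free.) The scalar model is nested between the sex-difference and
no-sex-difference models, and its −2LL falls between theirs on every
dataset.

### Profile-likelihood confidence intervals

Intervals are likelihood-based: the set of target values for which the
re-optimized deviance rises by at most $\chi^2_1(0.95) = 3.841$. For
every preset quantity (variance shares, bivariate shares, component
correlations, raw component entries, means, the implied phenotypic
correlation) the constraint is imposed *exactly* by solving one parameter
from the target — e.g. fixing $h^2_1$ solves
$A_{11} = h^2_1 (C_{11}+E_{11}) / (1 - h^2_1)$ — so the inner
optimizations are unconstrained in the remaining parameters and
warm-started along the search. Custom quantities (and the scalar mode)
fall back to a quadratic-penalty refit with an increasing penalty
schedule. Bounds are bracketed by doubling steps from the estimate and
then located by root bisection; a bound that cannot be bracketed within
the search range is flagged open rather than reported. Simulated coverage
of the 95% interval for $h^2$ at 500 pairs per group is checked to lie in
[0.93, 0.97] by the acceptance suite.

## The synthetic-data generator

`simulate_dataset()` draws each group's pairs from exactly the
multivariate normal the model assumes, with one random stream consumed in
the fixed group order MZf, DZf, MZm, DZm, so a seed pins the dataset
bit-for-bit and adding later groups cannot disturb earlier draws.
Missingness is applied per entry, missing completely at random, with an
optional per-twin block mode that removes both traits of a twin jointly
(emulating a whole questionnaire being absent). The generator emulates
the study design the package targets — four groups, bivariate continuous
phenotypes, group-specific means with sex differences, incomplete pairs —
and deliberately does **not** emulate Likert item-level measurement,
selection or participation bias, age structure, or informative
missingness. A green parameter-recovery test therefore establishes that
the estimator recovers the parameters of its own assumed world, not that
real questionnaire data satisfy those assumptions.

The packaged demonstration world `demo_sim_spec()` is an AE world (ACE
family with C = 0) on the standardized scale, calibrated to a large
adolescent twin study of well-being and optimism: female A-shares
0.444/0.311 with a bivariate genetic share of 0.663 of a phenotypic
correlation 0.403 (so the implied female genetic correlation is 0.719);
male shares 0.344/0.244, bivariate share 0.403 of r = 0.334; males score
0.12 and 0.31 SD higher on the two traits (the magnitudes implied by the
published descriptive table); 1200 pairs per group and 5% missing
entries. These defaults are stated once and not tuned: at this sample
size the test for quantitative sex differences has roughly 85–90% power
at $\alpha = 0.01$, so the expected ladder outcome — an AE model with sex
differences — is the typical but not guaranteed realization of the world.

## Degenerate inputs and edge cases

Pairs with no observed phenotypes are dropped at load (counted and
reported); zygosity or sex may never be missing. Fitting requires all
four groups non-empty; groups with fewer than ten pairs trigger a
warning. A zero phenotypic covariance makes the bivariate shares
undefined; they are reported as missing and flagged rather than invented
(covariance-scale CIs remain available via the `VA12`-type quantities).
Non-positive component variances make the corresponding correlation
undefined; this is an error in the standalone `genetic_correlation()`
and a missing value inside `standardize()`.

## Known limitations

Opposite-sex pairs and qualitative sex limitation (sex-specific genetic
factors) are out of scope, as are covariates, ordinal/threshold
measurement models, and more-than-two-trait or longitudinal extensions.
Confidence intervals are profile-likelihood only; no bootstrap. The
boundary-LRT mixture correction is not applied (the naive reference is
used, as in the published analyses the package mirrors); sensitivity
analyses can halve the reported p for a single-component boundary test by
hand.
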