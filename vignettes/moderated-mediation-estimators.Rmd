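---
title: "Estimating latent interactions in second-stage moderated mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating latent interactions in second-stage moderated mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modmedsem)
```

## The model

modmedsem studies the second-stage moderated mediation model with latent
variables. Four latent variables enter two structural equations:

$$M = a X + \zeta_M, \qquad
  Y = c X + b_1 M + b_2 Z + b_3 (M \times Z) + \zeta_Y,$$

so the indirect effect of $X$ on $Y$ through $M$, $a\,(b_1 + b_3 z)$, depends
on the moderator $Z$. The quantities a study reports are the interaction
coefficient $b_3$, the moderated mediation index $a b_3$ (the rate at which
the indirect effect changes per unit of the moderator), and the conditional
indirect effects at $z \in \{-1, 0, +1\}$ SD. Each latent variable is measured
with congeneric indicators,

$$x_j = \tau_j + \lambda_j X + \delta_j,$$

three each for $X$ and $Z$ and four each for $M$ and $Y$ (14 indicators in the
fixed column order `x1..x3, m1..m4, z1..z3, y1..y4`).

## The population model of the simulation study

`make_population_spec()` fixes the generating model: loadings
$(1, .65, .72)$ for $X$, $(1, .81, .53, .66)$ for $M$, $(1, .83, .79)$ for
$Z$, $(1, .68, .75, .83)$ for $Y$; all intercepts $0.5$; paths $a = .75$,
$b_1 = .56$, $b_2 = .48$, $c = .3$ with $b_3 \in \{0, .2, .4\}$ by design
cell; $\mathrm{Var}(X) = \mathrm{Var}(Z) = 1$ with
$\mathrm{Cov}(X, Z) \in \{0, .3\}$; both structural residual variances $0.36$.
Reliability is manipulated through the indicator error variances: $0.36$
(high) or $1.5$ (low) in **all four** blocks, with the structural residuals
held at $0.36$. Under this reading the closed-form population alphas are
$0.823 / 0.837 / 0.859 / 0.896$ (high) and $0.545 / 0.570 / 0.601 / 0.685$
(low), matching the reliabilities the design is calibrated to; the tests
assert these as exact oracles via `population_alpha()`.

Measurement-error distributions for the $M$- and $Z$-block indicators come in
five types (the $X$- and $Y$-block errors are always normal):

1. normal with the cell's error variance;
2. uniform on $[0, 1]$, centred to mean zero (natural variance $1/12$);
3. symmetric moderate kurtosis: $N(0,1) / \sqrt{\chi^2_5 / 3}$ (unit variance,
   excess kurtosis 6), rescaled to the cell's error variance;
4. symmetric high kurtosis: the same construction with a heavier divisor,
   $\chi^2_4$ by default (population kurtosis unbounded), rescaled likewise —
   the divisor degrees of freedom are exposed as arguments of
   `sample_error()` because the printed source of this construction is
   ambiguous;
5. slightly skewed: $\chi^2_1 - 1$ (variance 2, skewness $\sqrt 8 \approx
   2.83$), kept at its natural variance.

Types 2 and 5 keep their natural variances by default because rescaling would
change the skewness/kurtosis targets the types are meant to represent; a
`rescale_nonnormal` flag reproduces the variance-matched variant. Latent
means are zero and the structural equations carry no intercepts, so indicator
means come only from $\tau = 0.5$.

`population_moments()` gives the exact implied mean vector and covariance
matrix for normal-error cells, using the Gaussian moment identities
$E(MZ) = \mathrm{Cov}(M, Z)$,
$\mathrm{Var}(MZ) = \mathrm{Var}(M)\mathrm{Var}(Z) + \mathrm{Cov}(M, Z)^2$ and
$\mathrm{Cov}(MZ, \cdot) = 0$ for every first-order latent variable. It is the
oracle against which both the generator and the SEM engine's implied moments
are tested (agreement to $10^{-10}$).

## The four estimators

**Path analysis (PA)** — `fit_pa()` replaces each latent variable by the
unweighted mean of its indicators and fits the two structural equations by
least squares. By default the mediator and moderator composites are
mean-centred before forming the product; this leaves $\hat b_3$, the index
and the conditional indirect effects unchanged (they are invariant to the
centring) and only re-bases the lower-order coefficients, and a flag restores
the raw product. PA always completes, but ignoring measurement error
attenuates every estimate; the conditional indirect effects are evaluated at
the *composite* sample SD because composites are all this estimator sees.

**Product-indicator SEM (CPI / UPI)** — `fit_cpi()` and `fit_upi()` measure
the latent interaction with products of matched indicators. Matching sorts
each factor's indicators by loading and pairs rank with rank
(`match_indicators()`); with loadings $(1, .81, .53, .66)$ and
$(1, .83, .79)$ this pairs $(m_1 z_1), (m_2 z_2), (m_4 z_3)$ and leaves $m_3$
loading only on $M$. Indicators are mean-centred before multiplication. The
constrained variant ties every product parameter to the base parameters
(`cpi_constraints()`): $\lambda_{mz} = \lambda_m \lambda_z$;
$\mathrm{Var}(\delta_{mz}) = \lambda_m^2 \mathrm{Var}(M)\mathrm{Var}(\delta_z)
+ \lambda_z^2 \mathrm{Var}(Z)\mathrm{Var}(\delta_m)
+ \mathrm{Var}(\delta_m)\mathrm{Var}(\delta_z)$ with
$\mathrm{Var}(M) = a^2\mathrm{Var}(X) + \mathrm{Var}(\zeta_M)$;
$\mathrm{Var}(MZ) = \mathrm{Var}(M)\mathrm{Var}(Z) + (a\,\mathrm{Cov}(X,Z))^2$;
$E(MZ) = a\,\mathrm{Cov}(X, Z)$. The unconstrained variant keeps only the
latent-mean constraint; product loadings (except the first, fixed to 1 for
scale), product error variances, $\mathrm{Var}(MZ)$ and the covariances of
$MZ$ with $X$ and $Z$ are free — 8 extra parameters, which the tests assert.
Product-indicator intercepts are fixed at 0 in both variants (the centred
metric). Where the design is silent on the $MZ$ covariances we follow the
common unconstrained-approach practice: model-implied zeros under CPI, free
under UPI.

Both run on `ml_fit()`, a generic normal-theory ML engine for mean and
covariance structures: a model is a mapping from free parameters to
reduced-form matrices, so nonlinear constraints live inside the mapping and
the optimizer sees only free parameters. Identification fixes the first
loading of each factor at 1 and exogenous latent means at 0; intercepts are
free. Start values are deliberately population-agnostic (loadings 1, error
variances at half the sample variances, paths 0).

**Latent moderated structural equations (LMS)** — `fit_lms()` estimates the
interaction without product indicators. Conditional on the latent moderator
$Z = z$ the model is linear-Gaussian: $X \mid z$ is normal,
$Y = cX + (b_1 + b_3 z) M + b_2 z + \zeta_Y$, and the 14 indicators are
jointly normal with node-specific moments $\mu_k, \Sigma_k$. The marginal
per-case likelihood is a one-dimensional integral over $z$ approximated by a
Gauss–Hermite mixture $\sum_k w_k N(x_i; \mu_k, \Sigma_k)$.

Two numerical choices matter here:

* *Adaptive nodes.* The nodes are recentred per case on the posterior of $z$
  computed under the $b_3 = 0$ linearisation of the current parameter point.
  With $b_3 = 0$ that posterior is exact and the quadrature is **exact for
  every order $K$** — which is why `fit_lms(data, fix_b3 = 0)` agrees with
  the linear-SEM fit to $10^{-4}$ and the likelihood at $K = 16$ and $K = 64$
  differs by less than $10^{-6}$ (both are tested). Fixed-node quadrature at
  $K = 16$ would violate both, because the per-case posterior of $z$ is much
  narrower than the prior once three moderator indicators are observed.
* *Low-rank algebra.* $\Sigma_k = L \Psi(z_k) L' + \Theta$ with a constant
  $14 \times 3$ loading structure, so each node density uses a
  3-dimensional Woodbury identity rather than a 14-dimensional factorization.
  The kernel is compiled (RcppArmadillo). The tests check it against an
  independent plain-R oracle that integrates the full 14-dimensional
  conditional density over a dense moderator grid, to $10^{-3}$ on a 5-case
  likelihood (the oracle itself is converged to $10^{-8}$).

The default quadrature order is $K = 16$; because the adapted rule is already
near-exact at low order, the optimizer runs the bulk of its search at $K = 8$
and polishes at the requested $K$ (the two differ by $\sim 10^{-5}$ on this
model). Start values come from the linear-SEM ML solution with $b_3 = 0$.

Robust (sandwich) standard errors are $A^{-1} B A^{-1}$ with $A$ the
numerical observed information (forward second differences, relative step
$10^{-4}$) and $B$ the outer product of per-case scores (central differences,
relative step $10^{-5}$); the forward scheme for $A$ agrees with a central
one to $\sim 5 \times 10^{-4}$ relative at a tenth of the cost. Standard
errors for the index and the conditional indirect effects follow by the delta
method; LMS evaluates conditional effects at the *estimated latent* SD
$\sqrt{\hat\phi_Z}$ — an intentional asymmetry with PA, mirroring what each
estimator can see. `lr_test()` implements the two-step model-fit comparison
(fit the $b_3 = 0$ model, then the full model, refer $-2(\ell_0 - \ell_1)$ to
$\chi^2_1$), and `johnson_neyman()` draws confidence bands around the simple
slope $b_1 + b_3 z$ with analytic crossover points.

## Inference and the simulation loop

`bootstrap_fit()` provides case-resampling bootstrap standard errors and
percentile intervals (order statistics of the draws) for any estimator;
failed draws are excluded and counted rather than redrawn, keeping the
nominal number of draws interpretable. The study profile uses 100 draws.
`wald_test()` supplies the two-sided significance decisions; power and type-I
rates are defined from the Wald test at $\alpha = .05$ with whichever
standard error the estimator's flavor prescribes (bootstrap for PA/CPI/UPI,
robust for LMS), and interval-based decisions are available from the recorded
confidence limits.

Convergence is declared when the quasi-Newton optimizer reports success, or —
because with numerical gradients its internal tests can report "false
convergence" while standing exactly on the optimum, which happens
systematically for the LMS likelihood at very large $n$ — when the gradient
at the returned point is flat: below $10^{-3}$ on the (scale-free) ML
discrepancy, or below $10^{-6}$ relative to the log-likelihood magnitude for
LMS, both an order of magnitude above the finite-difference noise floor.

A *proper solution* is a converged fit whose estimated variances are all
non-negative and whose implied covariance is positive definite; the
completion rate is the proportion of proper solutions. This operationalizes
an undefined reporting convention in the source design; the choice is only
visible at low reliability and small samples, where the unconstrained
product-indicator model produces frequent Heywood cases — the qualitative
signature (UPI's completion collapsing toward ~0.6 at $N = 100$, low
reliability, while PA stays at 1) is asserted in the tests.

`run_cell()` runs one design cell with one reproducible substream per
replication (an integer hash of master seed, cell id and replication index),
so cells can be reproduced independently and in any order.
`summarize_cell()` computes relative bias (raw mean bias, flagged, where the
truth is zero, since relative bias divides by it), SE ratio
(mean SE / empirical SD), coverage, power or type-I rate, and completion,
over proper solutions only; the three conditional indirect effects are also
averaged into a single `ind` row, matching how such results are usually
tabulated. Conventional acceptability windows ($|RB| \le .10$, SE ratio in
$[0.9, 1.1]$, coverage $\ge .90$, type-I inside the binomial band around
$.05$) are attached as flags.

## Problem sizes

The package's own desk-scale profile, used by the test suite and by
`scripts/acceptance.R`: 100 generated datasets for the reliability checks;
200 path-analysis replications per cell (400 in the $N \le 200$ cells, where
the per-replication noise of $\hat b_3$ is largest, so every cell contributes
comparable Monte-Carlo error); 100 LMS replications for the power condition
and 200 for the type-I condition; bootstrap draws $B = 100$. Expected
Monte-Carlo error at this scale: about $\pm .008$ on the averaged PA relative
biases and $\pm .015$ on a proportion near $.05$. The full 1,000-replication,
all-cell grid runs through the same `run_design()` interface when more
compute is available.

## What the generator does and does not emulate

Passing tests show the estimators behave as expected for data generated from
this population model: congeneric indicators, a single latent interaction,
homogeneous error variances within reliability levels, and the five
error-distribution types. Real data add features the generator does not
emulate — unequal loadings configurations beyond the 3/4/3/4 layout,
correlated measurement errors, missing values, categorical indicators, and
structural misspecification — so conclusions about estimator rankings
transfer only insofar as those features are benign. Known limitations: no
factor-score path analysis, no parceling strategy for product indicators, no
Bayesian estimation, and no global fit indices beyond the log-likelihood
(the two-step likelihood-ratio comparison is the supported model-fit check).
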