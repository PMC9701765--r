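---
title: "Models and methods behind trophmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trophmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

trophmeta synthesizes experiments that compare a genetically diverse
plant stand (two or more genotypes) against a single-genotype control,
for responses measured at several trophic levels: plants themselves,
their antagonists (invertebrate herbivores, weeds, plant-feeding
nematodes, plant diseases), and the natural enemies of herbivores
(predators and parasitoids). This vignette documents the statistical
models, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Effect sizes

Each observation carries arm summaries $(M_t, M_c, sd_t, sd_c, n_t,
n_c)$. The standardized mean difference is

$$d = \frac{M_t - M_c}{sd_{pooled}}, \qquad
sd_{pooled} = \sqrt{\frac{(n_t - 1)\,sd_t^2 + (n_c - 1)\,sd_c^2}{m}},
\qquad m = n_t + n_c - 2,$$

bias-corrected to Hedges' $g = J(m)\,d$ with the exact correction
$J(m) = \Gamma(m/2) \big/ \left(\sqrt{m/2}\,\Gamma((m-1)/2)\right)$,
computed on the log-gamma scale. The familiar $1 - 3/(4m - 1)$ is the
first-order approximation of this factor and agrees to about three
decimals; we use the exact form because it is what the standard
meta-analysis software computes for this measure, and our unit tests
pin the two implementations against each other. The sampling variance is
Hedges' unbiased estimator

$$v = \frac{n_t + n_c}{n_t n_c} +
\left(1 - \frac{m - 2}{m\,J(m)^2}\right) g^2.$$

Observations with both arm SDs equal to zero are rejected at
validation, not imputed: the effect size is undefined on a degenerate
contrast. Signs are never flipped at any stage.

A known property worth stating: because $v$ depends on $g^2$,
inverse-variance weighting slightly attenuates very large effects
(planting a true standardized effect of $-2.1$ yields a mean estimate
around $-2.0$ at typical group sizes). This is inherent to the SMD
machinery, is shared by the reference implementations, and is why the
coverage calibration below plants means in the moderate range
$|\theta| \le 0.8$ where the variance approximation is reliable.

## Multilevel meta-regression

Effect sizes are modelled marginally as $y \sim N(X\beta, V)$ with

$$V = \mathrm{diag}(v_i)
 + \tau^2_{sp,phylo}\, Z_{sp} R Z_{sp}^\top
 + \tau^2_{sp}\, Z_{sp} Z_{sp}^\top
 + \tau^2_{study}\, Z_{st} Z_{st}^\top
 + \tau^2_{obs}\, I,$$

where $R$ is the Brownian-motion correlation matrix of the species
phylogeny (shared branch length from the root, unit diagonal, built
from a user-supplied Newick tree). Observations nest within studies via
the study intercept; the observation-level component absorbs residual
heterogeneity beyond the known sampling variances. The species effect
can be split into a phylogenetically correlated and an iid part; with
$R = I$ the two are algebraically interchangeable (a property the test
suite asserts), so users who prefer a single correlated term can fix
the iid part at zero via the `tau2` argument of `fit_meta()`.

Variance components are estimated by REML (or ML), optimized on the
log scale so non-negativity is structural. For one free component the
objective is solved by Brent search; for several, by Nelder-Mead with
relative tolerance $10^{-10}$, started from a moment-based split of the
excess variance plus two deterministic dispersed starts (factors of 10
up and down). Dispersed starts are deterministic rather than random so
that fitting never touches the RNG stream; ties are broken by the
highest restricted likelihood, then the smallest total heterogeneity.
`check_local_optimum()` audits any fit against 64 quasi-random
perturbations of the components. Numerically-zero components (below
$10^{-10}$) are snapped to zero.

Inference on coefficients and on linear combinations $c^\top\beta$
(`category_estimates()`) uses t statistics with $df = n - p$, matching
the t-type output of the standard software; no Knapp-Hartung or
sandwich adjustment is applied in this version. Likelihood-ratio tests
of fixed-effect terms refit both models by ML, because REML likelihoods
are not comparable across fixed-effect structures; comparisons of
variance components with identical fixed effects use REML. Empty
moderator cells are dropped from the design (with the level simply
absent from the output); rank-deficient designs raise an error naming
the aliased columns rather than silently pivoting.

## Genotype-number trends

The trend of effect sizes over the (log2-transformed) number of added
genotypes is fitted by generalized least squares with an exponential
variance function, $\mathrm{Var}(\varepsilon_i) = \sigma^2
e^{2\delta \mu_i}$, with the fitted values as variance covariate — the
default covariate of the standard `varExp` structure, since no
covariate is stated in the sources this reproduces. $\delta$ is
profiled by maximum likelihood (Brent search on $[-5, 5]$) and the
variance covariate iterated to $|\Delta\ell| < 10^{-8}$, with damping
after ten iterations to suppress two-cycles of the covariate update.
$\delta = 0$ reduces exactly to OLS. Slope inference uses $df = n - 2$.
Confidence bands come from the coefficient covariance with t quantiles;
grid points outside the observed range are flagged as extrapolation.
Error correlation structures (beyond heteroscedasticity) are not
implemented in this version, and the trend fits are unweighted by the
sampling variances — both stated scope choices.

## Piecewise structural equation models

Trophic interactions are analysed on subsets of co-measured effect
sizes: bi-trophic pairs (an antagonist response and a plant response
from the same study, site and diversity contrast) and tri-trophic
triples (natural enemy, herbivore, plant). The pairing key is
(study, site, number of added genotypes) — the finest key available in
all subsets; multiple observations of the same group within a key are
pooled by inverse-variance weighted mean first.

Each endogenous node gets one component model: a weighted mixed model
with the response's sampling variance as *fixed* residual variance
(prior weights $1/v_i$, residual scale fixed at 1) plus random study
intercepts, and a species intercept when the subset has several
species. This is the same marginal machinery as the meta-regression,
with no free observation-level component. Since every effect size
already encodes the diversity-versus-monoculture contrast, the binary
diversity indicator is constant within these subsets, and the path from
diversity into a node is the component model's intercept — the mean SMD
of that response in the subset. With the genotype-number exposure the
path is the slope on $\log_2(\text{genotypes})$ instead.

Global fit uses the d-separation basis set: all non-adjacent node
pairs, ordered causally, conditioned on the union of the parents of
both nodes; each claim is tested by the Wald t of the earlier node in a
component-style model for the later node, and the claim p-values
combine into Fisher's $C = -2\sum \ln p_i \sim \chi^2_{2k}$. For a
saturated DAG the basis set is empty and no global test is emitted.
Zero p-values are clipped at $10^{-16}$ with a warning. Indirect
effects are reported as products of path coefficients, without standard
errors. Because predictors that are themselves effect sizes carry
measurement error $v$, cascade paths are mildly attenuated (reliability
roughly $1/(1 + \bar v)$); at the reference conditions this is well
inside the recovery tolerances, but it is the reason path recovery is
assessed on averages over replicates.

## Publication bias

Within any established model specification, the regression test
appends the sampling variance $v_i$ (or its square root, behind the
`moderator` flag) to the moderators and reports its coefficient, t and
p — the multilevel analogue of the Egger test applied inside the model
rather than to raw effects. A constant $v$ column is collinear with the
intercept and raises a design error. The Rosenthal fail-safe number is
$N = \max(0, \lceil (\sum z_i)^2 / z_\alpha^2 - k \rceil)$ on
one-tailed z-scores, with the direction taken from the sign of the
pooled inverse-variance evidence by default (configurable); trim-and-
fill is deliberately excluded because it is defined only for models
without moderators.

## The synthetic-data generator

`simulate_observations()` draws, for each observation, a true effect
$\theta = \mu_{group} + b \log_2(\text{genotypes}) + u_{species} +
u_{study} + u_{obs}$, with species effects multivariate normal under
$\tau^2_{sp} [\,\lambda R + (1 - \lambda) I\,]$ ($\lambda$ =
`phylo_signal`, $R$ from a simulated Yule tree), and then draws actual
treatment and control samples with that standardized difference — so
the effect-size stage is exercised end to end rather than bypassed. A
fast mode draws $(g, v)$ directly from the SMD sampling distribution
for large calibration runs. The stream is forked per study (per-study
seeds drawn once from the global stream), so enlarging a dataset never
perturbs the studies already generated.

Reference conditions (the defaults): 150 studies contributing 1-5
observations each; group frequencies echoing the composition of the
experimental literature (plants 35%, herbivores 25%, diseases 20%,
natural enemies 10%, weeds 7%, nematodes 3%); true group means of
+0.344 (plant), -0.606 (herbivore), +0.778 (natural enemy), -0.071
(weed), -2.118 (nematode), -1.087 (disease) standardized units;
$\tau^2_{study} = 0.10$, $\tau^2_{obs} = 0.05$, $\tau^2_{sp} = 0.05$
with $\lambda = 0.5$ over 40 species; per-arm group sizes 4-30; raw
SDs 0.5-2; genotype additions drawn from {2, 3, 4, 6, 8}; genotype
slope 0 (trend analyses set it explicitly); tri-trophic paths
diversity→enemy +0.7, diversity→herbivore -0.8, diversity→plant +0.9
with zero cascade paths, and bi-trophic paths diversity→antagonist
-0.54, antagonist→plant -0.2, all with unit exogenous noise.

An optional censoring mechanism emulates publication bias by
suppressing, with a configurable probability, effects in a disfavoured
direction — either those with below-median sampling variance (the rule
used in the power checks) or the nonsignificant ones.

What the generator does *not* emulate: the real literature's exact
moderator frequencies and their confounding with trophic groups,
non-normal raw responses (counts, proportions), unbalanced designs
beyond unequal $n$, multiple sites per study, and digitization error
from figure extraction. Passing tests therefore demonstrate that the
estimators recover the parameters of the assumed hierarchical model,
not that any particular field dataset satisfies those assumptions.

## Problem sizes used by the test suite

The simulation-based checks use: 500 replicates at 60 studies for CI
coverage (planted means within $|\theta| \le 0.8$, see above); 500
replicates at 50 studies for the null calibration of the moderator LRT
and of the bias regression test (at 30 studies the ML chi-square is
visibly anticonservative, so calibration is assessed at a size where
the asymptotics hold); 500 replicates at 40 studies for the
d-separation global test under the true DAG; 200 replicates at 60
studies for SEM path recovery; and 200 replicates of the full
reference conditions (150 studies, raw two-arm generation) for
end-to-end recovery of the planted group means, fitted with the
iid-species random structure — the species-covariance split does not
affect recovery of fixed-effect means, and the phylogenetic kernel is
exercised separately against the reference implementation.

## Known limitations

* No Knapp-Hartung adjustment, robust variances, or Bayesian fitting.
* Trend models: heteroscedasticity only; no correlation structures;
  unweighted.
* SEM: no latent variables, no covariance-based fitting, no model
  search; indirect effects without standard errors.
* Fail-safe N: Rosenthal only (no Orwin or Rosenberg variants, no
  selection models).
* Reproducing published results from a curated dataset requires that
  dataset as input; the package ships no field data.
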