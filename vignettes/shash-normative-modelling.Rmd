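---
title: "Non-Gaussian normative modelling with SHASH hierarchical Bayesian regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-Gaussian normative modelling with SHASH hierarchical Bayesian regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A normative model estimates centiles of healthy variation in a
phenotype — say, the volume of a brain structure — as a function of
covariates such as age and sex, in the spirit of paediatric growth
charts.  Each individual is then scored by where their observation
falls in the fitted conditional distribution: the deviation
(*z-*) score.  Two features of real multi-cohort data make this hard:

1. **Non-Gaussian residuals.**  Many phenotypes are skewed and/or
   kurtotic conditional on age, so Gaussian centiles misplace the
   outer percentiles exactly where clinical interest is greatest.
2. **Site (batch) effects.**  Data pooled across scanners carry
   site-specific offsets that must be absorbed by the model, not
   leaked into the deviation scores.

`shashnorm` addresses both with a hierarchical Bayesian regression
whose likelihood is a sinh-arcsinh (SHASH) distribution and whose mean
carries a per-site random intercept.

## The SHASH family and the moment-standardised reparameterisation

The sinh-arcsinh transform
$\xi_{\epsilon,\delta}(x) = \sinh(\delta \sinh^{-1}(x) - \epsilon)$
maps a SHASH variable to a standard Gaussian; its inverse applied to
standard normal draws generates the family.  $\epsilon \in \mathbb{R}$
controls skew, $\delta > 0$ tail weight ($\epsilon = 0, \delta = 1$ is
the standard normal).  The density follows by change of variables and
is computed here entirely in log space (the $\cosh$ term overflows in
linear space long before the log-density becomes uninformative).

Adding location and scale the usual way
($\Omega = \sigma X + \mu$, the `SHASH_o` family) entangles the
parameters: $\epsilon$ moves the mean and $\delta$ the variance, so
their posteriors are strongly correlated and hard to sample.  The
`SHASH_b` reparameterisation first standardises the family by its
analytic moments,

$$\lambda_{\mu\sigma\epsilon\delta}(z) =
  \frac{\xi^{-1}_{\epsilon,\delta}(z) - m(1)}{\eta}\,\sigma + \mu,
  \qquad \eta^2 = m(2) - m(1)^2,$$

where the $r$-th non-central moment $m(r)$ has a closed form in
modified Bessel functions of the second kind ($K$):

$$m(r) = 2^{-r} \sum_{i=0}^{r} \binom{r}{i} (-1)^i
  e^{(r-2i)\epsilon/\delta}\, P\!\big((r-2i)/\delta\big), \qquad
  P(q) = \tfrac{e^{1/4}}{\sqrt{8\pi}}
  \big(K_{(q+1)/2}(\tfrac14) + K_{(q-1)/2}(\tfrac14)\big).$$

With this construction $E[B] = \mu$ and $\mathrm{Var}(B) = \sigma^2$
*exactly*, for every $(\epsilon, \delta)$: location/scale and shape
decouple, the parameters become interpretable, and the sampler mixes.
The two families are isomorphic — they describe the same set of
distributions — which the test suite verifies by an explicit affine
re-mapping.

### Numerical choices

* **Bessel terms.**  $K_\nu(1/4)$ grows astronomically with the order
  $\nu$ (this is the source of the family's numerical instability at
  small $\delta$).  `shash_P` works on the log scale, falling back to
  an upward recurrence with renormalisation when `besselK` overflows,
  and the moment sum is assembled by a sign-aware log-sum-exp.
* **The $\delta \ge 0.3$ floor.**  Sampling at $\delta < 0.3$ is
  numerically unstable, so the sampler's link is
  `delta_link(x) = softplus(10x)/10 + 0.3`; the factor 10 makes the
  map close to identity above zero.  The floor is a sampling device
  only — the density functions accept any $\delta > 0$.
* **Gradients.**  The log-joint gradient is analytic except for
  $\partial m(1)/\partial\delta$ and $\partial\eta/\partial\delta$,
  which involve the derivative of $K_\nu$ in its order (no closed
  form); these two scalar terms use central differences with relative
  step $10^{-6}$, which is far below the sampler's tolerance.
* **Extreme arguments.**  $\sinh^2$ terms are clamped at the largest
  representable magnitude so that log-densities and gradients at
  absurd leapfrog excursions stay finite (and get rejected) rather
  than turning into `NaN`.

## The hierarchical model

For subject $n$ with design row $\Phi_n$ (see below) and site $s(n)$:

* $\mu_n = \Phi_n w_\mu + \tau_{\mu,s(n)}$, with the site intercept
  sampled non-centred, $\tau_{\mu,s} = \mu_\tau + \sigma_\tau \nu_s$,
  $\nu_s \sim N(0,1)$, $\sigma_\tau \sim N^+(1)$ — the standard
  parameterisation for hierarchical NUTS.
* $\sigma_n = \mathrm{softplus}(\Phi_n w_\sigma + \tau_\sigma)$ —
  heteroskedastic scale as a linear fixed effect through a positivity
  link.
* Shape: model `Sb1` (and `So1`) use a single $\epsilon$ and a single
  raw $\delta$; model `Sb2` makes both linear functions of $\Phi_n$,
  allowing skew and tail weight to vary with age — necessary when the
  conditional skew changes sign across the lifespan.  Model `N` is the
  Gaussian special case.

Priors are standard normals on weights and intercepts, with the raw
tail parameter centred at 1 (pushing the sampler away from the
unstable low-$\delta$ region) and tighter scales (sd 0.2–0.3) on the
`Sb2` shape regressions, which act as implicit regularisation of the
shape trajectories.  Scale entries are standard deviations.

Batch effects enter the mean only.  Site offsets are not expected in
the variance or shape nearly as much as in the mean, and keeping them
out of $\sigma, \epsilon, \delta$ is precisely what makes the model
*conservative*: the shape of the distribution cannot silently absorb
site idiosyncrasies.  Sex is a covariate, not a batch dimension.

### Design matrix

`build_design_matrix` returns seven columns: a 5-column cubic B-spline
basis of age with two interior knots placed equally over the training
age range, age min–max rescaled to $[0,1]$, and the sex indicator.
Equal knot spacing is the simplest reproducible choice; the knot
record is stored in the fitted model and reused verbatim at prediction
time (out-of-span ages are clamped with a warning).  The linear age
column lies in the span of the spline basis plus an intercept, so the
weight vector is not fully identified — the Gaussian prior resolves
the redundancy, and all derived quantities (the $\mu$ curve, centiles,
z-scores) are identified.  Recovery tests therefore check the fitted
$\mu$ curve, not raw weights.  Responses are expected feature-wise
standardised (`standardise()`, statistics from the training split
only), which is what lets one set of priors serve phenotypes of very
different scales; an explicit per-response log-transform flag handles
strictly positive, severely skewed measures.

## Inference

No NUTS/HMC engine is available among this package's dependencies, so
the sampler is implemented here: the No-U-Turn criterion with slice
acceptance, dual-averaging step-size adaptation (target acceptance
0.8), windowed diagonal mass-matrix estimation during the 500-iteration
warmup, and a tree-depth cap of 10.  Defaults follow the study
conditions: 2 chains of 1500 iterations, 500 discarded as burn-in.
Runs with more than 5% divergent post-warmup transitions stop with an
error.  Chains are seeded deterministically, so results are exactly
reproducible.

Convergence is monitored with $\hat R$ (ratio of between- to
within-chain variability): the default is the split-chain
rank-normalised variant, with the classic Gelman–Rubin statistic
available behind a flag; both should sit near 1, with 1.1 the
conventional alarm threshold.  `rhat_trajectory` recomputes $\hat R$
on chain prefixes for convergence-versus-length analyses.

MAP estimation (BFGS on the unconstrained scale with the analytic
gradient, multiple jittered restarts) provides a cheap point
estimate; in practice MAP deviation scores and MCMC-mean deviation
scores agree to correlation above 0.99 on well-specified synthetic
data, which is why the point estimator is the default for scoring.
The MCMC z-score estimator is the mean of per-draw z-scores — the
simplest estimator consistent with averaging over the posterior.

## Deviation scores, centiles, and goodness of fit

The z-score is the inverse generating transform,
$z = \xi_{\epsilon,\delta}\!\big((y-\mu)/\sigma \cdot \eta + m(1)\big)$,
reducing to $(y-\mu)/\sigma$ in the Gaussian case.  Centile curves
push fixed Gaussian levels $g \in \{-3,\dots,3\}$ forward through
$\lambda$; the levels correspond to the 0.1, 2.3, 15.9, 50, 84.1,
97.7 and 99.9 percentiles, and monotonicity of $\lambda$ guarantees
the curves never cross.

Goodness of fit follows three complementary views: skew and excess
kurtosis of the z-scores (both 0 under a correct model), qq data
against standard normal quantiles, and — for site-effect removal — the
rank-based (Mann–Whitney, midrank ties) AUC of classifying every pair
of sites from the z-scores alone, reported as $|AUC - 0.5|$ so that 0
means sites are indistinguishable.

## The synthetic cohort generator

`simulate_cohort` draws cohorts exactly from the model's generative
process: ages uniform over 20–80 years, sex Bernoulli(0.5), equal-size
sites with mean offsets of sd 0.5 on the standardised scale, a
moderate age decline ($-0.5$ over the age range) and sex effect
($+0.3$) in the mean, mild age-linked heteroskedasticity
($\sigma \approx 0.6$ at the young end), and SHASH_b noise with
$\epsilon = 0.3$, $\delta = 1.2$ — a realistic degree of skew and
tail weight for "hard" phenotypes on the standardised scale.  The
default size, 5 sites of 200 subjects, keeps a full NUTS fit to a few
minutes on one CPU while leaving the shape parameters comfortably
identifiable.  `simulate_nonlinear_skew_cohort` makes $\epsilon$ run
linearly from $+0.8$ to $-0.8$ across the age range, emulating data
whose conditional skew changes sign — the regime that separates `Sb2`
from the constant-shape models.

What the generator deliberately does **not** emulate: real-world
phenotype scales (everything is standardised), unequal site sizes,
non-uniform age distributions, missingness, or site effects in
variance and shape.  Passing tests therefore demonstrate correctness
of the machinery under the model's own assumptions, not robustness to
every failure mode of real cohort data.

## A worked contrast

```{r, eval = FALSE}
library(shashnorm)

d <- simulate_cohort(sim_config(seed = 1))      # 5 sites x 200 subjects
fit <- hbr_fit(d, hbr_spec("Sb1"), method = "mcmc", seed = 1)
rhat(fit$samples, c("epsilon", "delta_raw"))

fit <- add_map(fit)
z <- zscores(fit)                               # point (MAP) scores
moments_report(z)                               # skew, excess kurtosis near 0
auc_matrix(z, d$site)                           # site entries near 0

cc <- centile_curves(fit, sex = 0)              # growth-chart centiles
```

Problem sizes used throughout the tests — cohorts of 300–1000
subjects, 2–5 sites, chains of 700–1500 iterations, and a 5-replicate
coverage study — were chosen as the smallest designs at which the
shape parameters are clearly identified and coverage statements are
meaningful.

## Known limitations

* Tail flexibility is bounded by the SHASH family itself; mixture
  tails are out of scope.
* Batch effects are one-dimensional (site) and enter the mean only.
* The `Sb2` gradient evaluates per-subject Bessel terms, so NUTS on
  `Sb2` is markedly slower than `Sb1`; MAP estimation is the practical
  route for `Sb2` at desk scale.
* Transfer to unseen sites uses the group-mean offset; no
  informed-prior transfer learning is implemented.
* Variational inference is not implemented; MCMC and MAP are the two
  inference routes.
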