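---
title: "Zero-inflated additive modelling of longline survey catch rates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-inflated additive modelling of longline survey catch rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zigamsurvey)
```

## The problem

Fisheries-independent longline surveys of sharks produce count data with far
more zero hauls than a Poisson process would explain: on most cruises no
individual of a given species is caught at all, either because the species is
genuinely absent (a structural zero) or because a Poisson catch process
happened to produce zero. `zigamsurvey` analyses such surveys at the cruise
level: fishing sets within a cruise are not independent, so catches and hook
counts are summed and environmental covariates averaged per cruise, and the
catch rate is standardized by a log-effort offset.

## The mixture model

For cruise $i$ with catch $y_i$, effort $E_i$ (hooks) and covariates $x_i$:

$$
y_i \sim
\begin{cases}
0 & \text{with probability } 1 - p_i \\
\mathrm{Poisson}(\mu_i) & \text{with probability } p_i
\end{cases}
$$

with

$$
\log \mu_i = \log E_i + \beta_0 + \textstyle\sum_j f_j(x_{ij}) + \text{site}_i,
\qquad
\mathrm{logit}\, p_i = \gamma_0 + \textstyle\sum_j g_j(x_{ij}).
$$

Throughout the package $p_i$ is the probability of the **regular**
(non-zero-inflated) state. Three model families are fitted:

* **GAM** — plain Poisson ($p_i \equiv 1$);
* **ZIGAM** — the unconstrained mixture, zero and count components each with
  their own additive structure;
* **COZIGAM** — the constrained mixture with
  $\mathrm{logit}\, p_i = \alpha + \delta \log \mu_i$, coupling presence to
  abundance.

The smooths $f_j, g_j$ are low-rank thin-plate regression splines (eigen-
truncated, sum-to-zero constraint absorbed by column centering). Default
basis dimension is $k = 10$ for one-dimensional smooths and $k = 25$ for the
single bivariate year–month smooth of the SPT2 spatiotemporal model. The
bivariate smooth is isotropic on coordinates standardized to unit variance —
year and month live on incommensurate scales, and a single shared penalty
after standardization is the simplest structure consistent with one smooth
function of both. Month is treated as a free (non-cyclic) covariate so that
its endpoints are not forced equal.

## EM fitting

A zero observation's state is unobserved, so the mixture is fitted by EM.
The E-step computes the responsibility of the regular state for each zero,

$$
z_i = \frac{p_i e^{-\mu_i}}{(1 - p_i) + p_i e^{-\mu_i}},
$$

($z_i = 1$ for positives); the M-step performs a penalized weighted Poisson
fit (prior weights $z_i$) and a penalized binomial fit to the fractional
responses $z_i$. Each component fit is a penalized IRLS (P-IRLS) capped at
200 inner iterations. EM stops when the relative change in the observed-data
penalized log-likelihood falls below $10^{-6}$, with a hard cap of 250
iterations (the convergence flag is reported either way). The observed-data
penalized log-likelihood is non-decreasing across iterations and the test
suite asserts this on every fixture.

For COZIGAM the M-step maximizes the expected complete-data penalized
log-likelihood jointly in $(\beta, \alpha, \delta)$ by BFGS with analytic
gradients, accepting the update only if it improves the objective — a
generalized EM step, so monotonicity is preserved.

Numerical guards: linear predictors are clipped at $\pm 30$ (protects
all-zero responses and near-separation in the zero model); responsibilities
are clipped to $[10^{-10}, 1 - 10^{-10}]$; Cholesky solves fall back to a
jittered factorization when a smooth is numerically unidentifiable at
extreme smoothing parameters.

## Model evidence (logE) and its conventions

Models are compared — and smoothing parameters chosen — by the
Laplace-approximated log marginal likelihood,

$$
\log E = \ell_p(\hat\theta) + \tfrac{p}{2}\log 2\pi
 - \tfrac12 \log \lvert H \rvert + \text{prior constants},
$$

where $\ell_p$ is the penalized observed-data log-likelihood at the mode and
$H$ the negative Hessian of $\ell_p$ (analytic for GAM and ZIGAM; numerical,
via `pracma::hessian`, for the COZIGAM parameterization, whose
$\beta$–$\delta$ coupling makes the analytic form error-prone). Smoothing
penalties are treated as Gaussian priors on the penalty range space, with
their normalizing constants
$\tfrac12(r_j \log \lambda_j + \log\lvert S_j\rvert_+ - r_j \log 2\pi)$
included, so that logE is comparable across $\lambda$ and across model
types.

Two further conventions make the comparison well defined:

* Intercepts and factor coefficients carry flat improper priors; they are
  common to every model compared.
* Smooth null-space coefficients (the linear parts the wiggliness penalty
  cannot see) and the COZIGAM slope $\delta$ carry **proper**
  unit-information-scaled Gaussian priors with precision
  $0.01 \cdot \overline{x^2}$. With fully flat priors on parameters not
  shared between candidate models, Bayes-factor-style comparisons are
  arbitrary, and in practice a pure-noise smooth raised logE about half the
  time; under the proper weak priors an extra term must earn its evidence.
  The priors are weak enough that fits are essentially unshrunk (the linear
  component changes by $O(10^{-3})$ on the link scale).

Smoothing parameters maximize this same logE by a coordinate-wise grid
search over $\lambda \in 10^{\{-2,\dots,4\}}$ (two passes when a model has
several smooths), with warm-started refits. Using one criterion for
smoothness selection and model selection keeps every comparison on a single
scale; the grid resolution is deliberately coarse — evidence differences
well below one unit never drive a structural decision.

Ill-conditioned Hessians are ridge-stabilized before the log-determinant is
taken, with a warning.

## Diagnostics

Deviance explained uses the mixture deviance,
$1 - (\ell_{sat} - \ell_{model}) / (\ell_{sat} - \ell_{null})$, with the
saturated mixture placing each positive at $\mu = y$ with $p = 1$ and each
zero in the structural state; the null model is the intercept-only model of
the same family. The adjusted coefficient of determination is

$$
R^2_{adj} = 1 - \frac{n - 1}{n - \mathrm{edf}_{total}}\,(1 - R^2_{dev}),
$$

a documented, fixed convention (the original analysis library's exact
formula is not published). Per-term Wald $\chi^2$ statistics come from the
coefficient block and its posterior covariance, tested on the term's
effective degrees of freedom; the reported reference df equals the edf under
this convention. Partial effects are centered link-scale smooths with
Bayesian $\pm 1.96\,\mathrm{SE}$ bands.

## Covariate screening

Before modelling, all covariate pairs are screened on pairwise-complete
observations: Pearson's $r$ with a Student-$t$ test on $n-2$ df, a Fisher-Z
95% interval, and Spearman's $s$ (average ranks). A pair is *problematic*
when (i) $p < 0.05$, (ii) the larger absolute interval endpoint is
$\ge 0.3$, and (iii) either $|s| \ge 0.3$ or the smaller absolute endpoint
is $\ge 0.3$. Flagged pairs never enter the same model; the forward stepwise
search enforces this as a hard constraint. No multiple-testing correction is
applied across pairs, matching the screen's descriptive role.

## Model-selection workflow

* **Basis dimension**: univariate ZIGAMs over a grid
  $k \in \{4, 6, 8, 10, 12\}$; the evidence-maximizing $k$ wins, ties to the
  smaller $k$.
* **Model type**: GAM/ZIGAM/COZIGAM fitted univariately per predictor;
  failures are recorded as missing entries, never raised; the type that wins
  the most cells is chosen, ties to ZIGAM.
* **Spatiotemporal structure**: SPT1 (site factor + independent year and
  month smooths) vs SPT2 (site factor + one shared bivariate year–month
  smooth).
* **Environmental model**: forward stepwise from the site factor and offset;
  each step adds the admissible candidate with the highest logE and the
  search stops at the first step with no improvement (ties are not
  explored; the trace records every evaluation, so alternative paths can be
  audited).

## The synthetic survey generator

The survey's raw data are not public, so the package ships a generator that
reproduces the study conditions and retains its truth for recovery tests:

* **Design**: 518 nearshore cruises split evenly between sites BV and PA
  (weekly sampling, September 2005 – December 2011, 400 hooks per cruise)
  plus 38 mid-shelf (CS) cruises of 200 hooks.
* **Covariates**: sea surface temperature follows an annual sinusoid
  (austral-summer peak, $27.8 + 1.3\cos(2\pi(m-3)/12)$ °C, noise SD 0.7);
  the lunar day is deterministic in the date; the remaining covariates come
  from a Gaussian copula conditioned on the normal scores of temperature and
  lunar day, pushed through monotone marginal transforms. Because the
  transforms are monotone, the latent correlations $2\sin(\pi s / 6)$
  deliver the target Spearman correlations — the same quantities the screen
  tests. Default targets reproduce the published pairwise structure
  (e.g. temperature–visibility 0.60, visibility–wind speed −0.52,
  pluviosity–wind direction 0.35, tidal amplitude–lunar day −0.23).
* **Catches**: per species, a Bernoulli regular-state indicator followed by
  a Poisson count with log-effort offset. The three default species exercise
  distinct smooth shapes — a month sinusoid (nurse-like), a monotone
  temperature effect (blacknose-like), a quadratic tidal-amplitude effect
  (tiger-like) — and each zero process has its own covariate effect whose
  shape deliberately differs from the count smooth, so the zero-inflation is
  covariate-driven yet structurally independent of $\mu$. Regular-state
  baseline probabilities are 0.22 / 0.15 / 0.10 (moderate, identifiable
  zero-inflation); baseline log catch rates are then calibrated by
  root-finding on the realized covariate table so the expected
  positive-catch proportions equal the survey's published 16%, 9% and 6%.
  The abundance scale is calibration-derived: the survey publishes no
  per-hook rate parameters.
* **Individuals**: lengths are rejection-sampled truncated normals with the
  published per-species mean, SD and range; sexes are Bernoulli in the
  published male fraction; each simulated capture carries its cruise's date
  and site.

What the generator does **not** emulate: within-cruise set-level structure
(generation is at the analysis unit), spatial point patterns within sites,
covariate missingness, gear effects, and any coupling between abundance and
length structure. Passing recovery tests therefore demonstrates that the
estimation machinery recovers known truths under the study's design — not
that the field data satisfy the model.

## Assemblage statistics conventions

Sex-ratio goodness-of-fit tests are uncorrected chi-squares (no Yates
correction — the published worked values match the uncorrected statistic
exactly). Length comparisons between sexes use Welch's two-sample $t$;
between years/quarters, Kruskal–Wallis with tie correction, followed by the
mean-rank multiple-comparison procedure with critical difference
$z_{1-\alpha/k(k-1)} \sqrt{N(N+1)/12\,(1/n_i + 1/n_j)}$. A utility
reconstructs integer sex counts from published rounded ratios and errors on
ambiguity; the published tiger-shark line (ratio 0.69:1 of 56 sexed
individuals) is internally inconsistent — no integer split reproduces it —
and is deliberately excluded from any worked-value check.

## Problem sizes used by the test suite

Unit fixtures use 200–2 000 cruises; parameter-recovery and calibration
checks use the full 556-cruise design over 10–20 replicate seeds; basis
dimensions 4–8 and a seven-point $\lambda$ grid keep each fit around a
second. These sizes were chosen so the complete suite exercises every code
path at meaningful power while remaining comfortable to run interactively.

## Known limitations

* No negative-binomial or Tweedie count components, no partially
  constrained COZIGAM, no spatial random fields.
* The Laplace evidence with the conventions above is a consistent internal
  yardstick; absolute logE values are not comparable to other software's.
* COZIGAM reporting edf for the count component comes from the weighted
  Poisson representation at convergence (an approximation; $\alpha, \delta$
  add two parameters).
* The stepwise search is greedy; it stops at the first non-improving step
  and does not explore ties.
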