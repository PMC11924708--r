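---
title: "Methods: SAM-prior borrowing in a Bayesian group-sequential noninferiority design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SAM-prior borrowing in a Bayesian group-sequential noninferiority design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Medical-device trials often follow earlier device generations with similar
mechanisms, so historical control-arm data are available and worth
borrowing — if the historical and current control populations actually
agree. `samgsd` implements a Bayesian group-sequential noninferiority
design for a binary endpoint in which the amount of historical borrowing is
decided *by the data at each interim*, through a Self-Adapting Mixture
(SAM) prior, rather than fixed in advance.

Notation: $\theta_t$, $\theta_c$, $\theta_h$ are the event rates in the
current test arm, current control arm and historical control arm; $M$ is
the noninferiority margin on the risk-difference scale and $\Delta$ the
congruence margin — the smallest difference between $\theta_c$ and
$\theta_h$ that is considered clinically meaningful. Noninferiority is the
alternative $H_1: \theta_t - \theta_c < M$, and the trial monitors
$p = \Pr(H_1 \mid D_c, D_t)$ at each analysis.

## MAP prior elicitation from historical studies

Aggregated historical studies $(n_j, y_j)$ enter a hierarchical binomial
model

$$y_j \sim \mathrm{Bin}(n_j, \theta_j), \qquad
  \mathrm{logit}(\theta_j) \sim N(\mu, \tau^2),$$

with weakly informative hyperpriors $\mu \sim N(0, 2^2)$ and
$\tau \sim \text{Half-Normal}(1)$ (all configurable through
`map_mcmc_control()`). These are the de-facto defaults for
meta-analytic-predictive (MAP) priors on binary endpoints: the $\mu$ prior
is flat over any plausible logit rate, and Half-Normal(1) allows
substantial between-study heterogeneity without favoring it. The MAP prior
for a new exchangeable control arm is the predictive distribution
$\mathrm{logit}^{-1}(\mu + \tau z)$, $z \sim N(0,1)$, sampled by MCMC
(JAGS, four chains, 2000 adaptation and 2500 retained iterations per chain
by default). Convergence is gated on split-$\hat R < 1.01$ for $\mu$ and
$\tau$; a failing fit retries with doubled tuning and then errors with its
diagnostics rather than returning an unusable posterior.

Heterogeneity is quantified by Cochran's $Q$ with fixed-effect
inverse-variance weights and $I^2 = \max(0, (Q - \mathrm{df})/Q)$, on the
logit scale by default (effect sizes from `metafor::escalc`, 0.5
continuity correction for zero cells). The raw-proportion scale is
available because published $I^2$ values do not always state their scale:
for the packaged four-study example the logit scale gives 90.8% and the
raw scale 91.2%, both "substantial heterogeneity" and close to, but not
exactly, a published rounding of 92%.

The MCMC sample is then compressed into a parametric **beta mixture** by
expectation-maximization (`fit_beta_mixture_em()`): method-of-moments
initialization on a k-means split of the draws under a fixed seed,
responsibilities in the E step, weighted maximum-likelihood beta fits
(BFGS with analytic digamma gradients) in the M step. The log-likelihood
trace is retained and is monotone by construction; a component whose
weight collapses below $10^{-4}$ triggers a refit with one component
fewer. Two components are the default (adequate for unimodal,
right-skewed MAP posteriors); `"auto"` selects 1–4 by AIC.

## The SAM prior

The congruence test compares $H_0: |\theta_c - \theta_h| < \Delta$ against
$H_1: |\theta_c - \theta_h| \ge \Delta$ through a likelihood-ratio odds
evaluated at plug-in points: with $\hat\theta_h$ the MAP-EM mixture mean
(fixed at design time),

$$R = \frac{L(D_c \mid \theta_c = \hat\theta_h)}
           {\max\{L(D_c \mid \hat\theta_h + \Delta),
                  L(D_c \mid \hat\theta_h - \Delta)\}},
  \qquad w = \frac{R}{1 + R},$$

with the binomial likelihood evaluated in log space (`sam_weight()`). The
SAM prior mixes the informative MAP-EM component with a weakly
informative component:

$$\Pr(\theta_h) = w \Pr(\theta_h)_{\text{MAP-EM}}
  + (1 - w) \Pr(\theta_h)_{\text{weak}}.$$

The proportionality between $w$ and $R$ in some write-ups is read here as
the equality $w = R/(1+R)$; anything else leaves $w$ undefined.

Two shape facts about $w$ worth knowing when reading simulation output:
the pointwise maximum of $w$ over data configurations is about 0.53 (not
1), reached when the observed control rate equals $\hat\theta_h$; and the
*unconditional* average of $w$ over binomial draws at a congruent truth
sits slightly below one half (about 0.43 at $n = 398$), while the average
among trials that continue past an interim — the quantity a trial report
tabulates — is closer to 0.47–0.5, because trials with extreme control
data tend to stop.

### The weak component

The weak component defaults to the unit-information robust-MAP form

$$\mathrm{Beta}(\hat\theta_h \cdot m + 1,\; (1 - \hat\theta_h)\cdot m + 1),
  \qquad m = \texttt{ess\_weak} = 1.$$

The `+1` is deliberate, not cosmetic. A plain mean-matched
$\mathrm{Beta}(\hat\theta_h m, (1-\hat\theta_h)m)$ with $m = 1$ has both
shapes below 1, so its density is unbounded at the support boundary and
the local-information integral behind the ELIR effective sample size
*diverges* there — a trimmed quadrature returns large negative garbage,
and every downstream ESS-driven adaptation would inherit it. Keeping both
shapes above 1 bounds the density, keeps the ELIR finite, and matches
common robust-MAP practice. The plain form remains available
(`unit_information = FALSE`) for uses that never touch the ELIR.

## Effective sample size (ELIR)

`elir_ess()` computes
$\mathrm{ESS} = E_\theta\{ i(p(\theta)) / i_F(\theta) \}$ with
$i(p(\theta)) = -\,\mathrm d^2 \log p(\theta)/\mathrm d\theta^2$ computed
analytically from the mixture components and adaptive quadrature for the
expectation (relative tolerance $10^{-6}$; integration trimmed to
$[10^{-6}, 1 - 10^{-6}]$ with the quadrature error reported whenever a
shape is at or below 1). The binomial unit information
$i_F(\theta) = 1/(\theta(1-\theta))$ is the default: it reproduces the
canonical closed form $\mathrm{ESS}(\mathrm{Beta}(a,b)) = a + b$ for
$a, b > 1$. A $1/\theta$ (Poisson) variant is provided for sensitivity
analysis, since published ESS tables do not always say which unit
information they used; no acceptance-grade comparison is made on ESS for
that reason. Note the closed form genuinely requires $a, b > 1$ — the
identity behind it integrates $E[(1-\theta)/\theta]$, which diverges at
$a \le 1$ (the ELIR of the uniform prior is 0, not 2).

For the packaged example the MAP-EM mixture has ELIR ESS 38.3, and the
assembled SAM prior about 13.5 at $w = 0.5$ — deliberately small relative
to the 983 historical patients, reflecting the 91% heterogeneity.

## Group-sequential scaffold

The frequentist scaffold uses Hwang-Shih-DeCani error spending
$f(t) = \text{level}\cdot(1 - e^{-\gamma t})/(1 - e^{-\gamma})$ with
$\gamma_\alpha = -4$ (efficacy) and $\gamma_\beta = -2$ (futility) at
equally spaced information fractions. Bounds are computed by the canonical
recursive numerical integration for sequential Z statistics: the
continuing-path subdensity is propagated on a trapezoid grid (601 nodes
per analysis by default; results are stable to $5\times10^{-4}$ on the Z
scale between 401 and 1001 nodes) on the score scale $W_k = Z_k\sqrt{t_k}$,
where increments are independent normals, and each bound is solved to
$10^{-9}$ by root bracketing. Futility bounds are solved under the drifted
design alternative; the drift — and hence the information inflation and
the maximum sample size — is the value at which the futility and efficacy
bounds meet at the final analysis.

**Binding futility is the default.** Both conventions are implemented;
binding (the futility bounds honored in the alpha-spending recursion, the
two bound sets solved jointly by fixed-point iteration) is the package
default because it is the convention consistent with the worked example
this package documents: with three equally spaced analyses it yields
upper bounds (2.79, 2.29, 1.64), lower bounds (−0.42, 0.64, 1.64) and an
inflated maximum of 2,386 from a one-stage 2,282, whereas the non-binding
convention puts the final bound at 1.68 and the maximum at 2,452. The
choice is a single flag (`binding = FALSE`) for designs that must not rely
on stopping for futility.

The one-stage total uses the unpooled normal-approximation formula per arm
$(z_{1-\alpha} + z_{1-\beta})^2\, 2\theta(1-\theta) / M^2$, with the
control rate rounded to 2 decimals by default (`rate_digits`): sizing at a
round planning rate (0.18 rather than 0.179) is how such calculations are
conventionally reported, and it is what the worked example's 2,282
corresponds to. Per-analysis cumulative enrollment targets are
$\lceil n_{\max} t_k \rceil$.

Bayesian decision thresholds are $\Phi(Z)$ of the bounds. Ties belong to
the continuation region (the continuation interval is closed on both
ends); the final rule is $p > \Phi(z_{\text{final}})$ for noninferiority.

## The interim algorithm and the simulation engine

`simulate_trial()` executes, per trial:

1. Stage 1 enrolls the first planned block split exactly 1:1 and tests
   with the weakly informative priors on both arms — no borrowing before
   the first congruence assessment. The test arm's prior is uniform
   $\mathrm{Beta}(1,1)$ throughout (borrowing applies to the control arm
   only).
2. At a continuation interim, $w$ is recomputed from the *cumulative*
   current-control data (per-stage data would discard information and make
   $w$ noisier; a `fixed` mode freezes $w$ instead, giving the static
   comparator design), the SAM prior is assembled, and its ELIR ESS taken.
3. The next stage's planned increment is reduced by the ESS rounded to
   the nearest integer — the prior substitutes for that many patients —
   and each newly enrolled patient is assigned to control with probability
   $\frac{r}{r+1}$, $r = \max(N_c\eta - \mathrm{ESS}, 0)/(N_t\eta)$.
   The assignment is an independent Bernoulli draw per patient because the
   formula defines a probability, not a deterministic quota.
4. Posteriors absorb all cumulative data (control: SAM prior; test:
   uniform), $p$ is recomputed, and the decision rule applies, through the
   final analysis. Because every post-interim stage is ESS-reduced, a
   completed trial enrolls slightly fewer than the design maximum; the
   engine reports patients actually enrolled.

$\eta = 1/3$ per stage (two interims plus final) matches the per-analysis
targets 796/1,591/2,386 of the worked example. Reported ESS per trial is
the mean of the SAM-prior ELIR over the interims the trial actually
reached; interim weights are tabulated only for trials that reach the
assessment, which is what published per-interim weight columns mean.

`run_scenarios()` gives every trial its own deterministic seed derived
from (master seed, scenario index, trial index), so any scenario or trial
is individually reproducible and the whole table is bitwise-reproducible.

## The scenario grid as a synthetic-data generator

`default_scenarios()` encodes the study conditions: historical rate
$\hat\theta_h = 0.179$, $\Delta = 0.02$, $M = 0.04$; the true current
control rate takes offsets $\{0, -\Delta, -1.5\Delta, -2\Delta\}$, crossed
with $H_0$ ($\theta_t = \theta_c + M$, a device exactly at the margin) and
$H_1$ ($\theta_t = \theta_c$, an identical device). Outcomes are
independent Bernoulli events at constant true rates. What this emulates is
the *sampling* behavior of a two-arm trial under controlled
prior-data-conflict levels; what it does not emulate is anything a real
phase-4 trial adds on top — enrollment drift over calendar time,
site-level clustering, covariate imbalance, or misreported historical
summaries. Passing operating-characteristic tests therefore demonstrates
that the design's error control and borrowing adapt as intended under
clean binomial sampling, not that a particular real trial is protected
against structural biases.

## Numerical choices, in one place

- Mixture quantiles: bisection on the mixture CDF to $10^{-8}$.
- Posterior probability of noninferiority: one-dimensional adaptive
  quadrature of $F_t(\theta_c + M) f_c(\theta_c)$ to absolute $10^{-6}$
  (deterministic and fast enough to sit inside the simulator; checked
  against paired Monte-Carlo sampling in the tests).
- Mixture conjugate updates: beta-binomial marginal likelihoods in log
  space; components below $10^{-8}$ weight dropped at prior assembly.
- ELIR: analytic curvature, adaptive quadrature, $\epsilon$-trim
  $10^{-6}$ with reported truncation error when shapes are at or below 1;
  divergent integrals are an error, never a number.
- Boundary solver: 601-node trapezoid grids, roots to $10^{-9}$;
  fixed-point iteration between the bound sets to $10^{-8}$ when binding;
  maximum sample size $\lceil n_{\text{fixed}} \cdot \text{inflation}
  \rceil$, bumped to even so a 1:1 split is whole.
- EM: relative log-likelihood tolerance $10^{-8}$, iteration cap 500,
  fixed-seed k-means initialization.

## Problem sizes used by the checks

The packaged test suite runs the operating-characteristics comparison at
200 simulated trials per scenario with tolerances of three binomial
standard errors at that size, and the full eight-scenario grid at 50
trials per scenario as an end-to-end completeness check; these sizes make
the default suite complete in well under a minute of simulation time
while leaving the comparisons statistically meaningful. The full published
table (1,000 trials per scenario, both design versions) is a single
command — `samgsd replicate-example --n-sims 1000 --seed 1 --out results/` —
and takes on the order of minutes on one core.

## Known limitations

- Binary endpoints only; continuous or count endpoints would need their
  own conjugate family and unit information.
- Historical information enters as aggregated counts; individual-level
  covariate matching or propensity weighting is out of scope.
- The congruence weight is a plug-in likelihood ratio, not a posterior
  probability of the congruence hypothesis; that is what makes it cheap
  and interpretable, but it ignores uncertainty in $\hat\theta_h$.
- The printed 95% credible interval of the published example's MAP-EM
  mixture has upper limit 0.344 when recomputed from its own printed
  components (its CDF at 0.33 is 0.972); a published 0.33 is consistent
  with a quantile of the pre-EM MCMC sample instead. The package reports
  what the mixture arithmetic gives.
- With `weight_mode = "fixed"` the SAM prior is the same object at every
  interim, so its reported ESS is constant within a trial by
  construction.
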