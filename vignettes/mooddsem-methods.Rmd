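---
title: "Modelling weekly insomnia and mood dynamics in bipolar disorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling weekly insomnia and mood dynamics in bipolar disorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mooddsem)
```

## The scientific problem

People with bipolar disorder report weekly symptom questionnaires through
online monitoring platforms for months or years: the Quick Inventory of
Depressive Symptomatology (QIDS-SR16) and the Altman Self-Rating Mania Scale
(ASRM). Two questions recur in this literature. Stable differences: who runs
at a higher typical level of depression, insomnia or (hypo)mania, and who
fluctuates more? Dynamics: when someone sleeps worse than usual one week,
does their mood worsen the next week, and vice versa — and does the strength
of that coupling differ across people?

Answering both at once requires separating *between-person* variation (one
person's stable level versus another's) from *within-person* variation (this
week's deviation from one's own stable level). `mooddsem` implements the
dynamic structural equation model (DSEM) family used for such weekly panels:
a multilevel bivariate AR(1) model in which every dynamic parameter is a
person-specific random effect.

## Scales

Insomnia cannot be modelled jointly with mood if the mood scales themselves
contain sleep items, so the scores are constructed to be disjoint:

* **Insomnia** (0–9): the sum of the three QIDS insomnia items (sleep onset,
  sleep maintenance, early-morning waking).
* **Depression** (0–27): the standard nine-domain QIDS total with those
  three items removed; the sleep domain is retained as the hypersomnia item
  alone, preserving the 0–27 frame. The instrument's published domain rule
  (maximum within the sleep, appetite/weight and psychomotor domains) is
  kept. Whether the hypersomnia item should be retained or the whole sleep
  domain dropped (0–24) is a genuine ambiguity; both are exposed through
  `scoreQidsDepression(sleepDomain=)`, with `"hypersomnia"` as the default
  because only the three insomnia items are explicitly removed.
* **(Hypo)mania** (0–16): the ASRM total with the reduced-need-for-sleep
  item excluded (the 0–20 total is available via `includeSleep = TRUE`).

Partial item missingness within an answered week is rejected rather than
imputed: weekly prompts deliver whole questionnaires, so missingness is
treated as whole-week.

## The model

For person $i$, process $j$ (depression, insomnia or (hypo)mania) and week
$t = 1,\dots,T$ on a common grid,

$$Y_{ijt} = \mu_{ij} + s_{ij}\,(t - \bar t) + y_{ijt}, \qquad
  y_{ijt} = \sum_k \phi_{jk,i}\, y_{ik,t-1} + e_{ijt}, \qquad
  e_{ijt} \sim N(0, \pi_{ij}),$$

with $\bar t = (T+1)/2$. The person-level parameters are

* $\mu_{ij}$ — the *individual mean*, the stable level (score points);
* $s_{ij}$ — a small linear slope (points/week), a nuisance term absorbing
  the slow population-level drift seen in long monitoring panels;
* $\phi_{jj,i}$ — *inertia* (carry-over): how much of this week's deviation
  survives to next week (dimensionless, $|\phi|<1$ for stationarity);
* $\phi_{jk,i}$, $j \ne k$ — *cross-lagged effects*: the effect of last
  week's deviation in process $k$ on this week's deviation in process $j$
  (raw scale: points per point);
* $\ln \pi_{ij}$ — the log *innovation variance*: how big the weekly shocks
  are. The log scale keeps the variance positive when modelled as a random
  effect.

Stacked into $\eta_i$ (4 parameters per process in univariate models, 10 in
bivariate ones), the between-person model is

$$\eta_i = \gamma + B x_i + u_i, \qquad u_i \sim N(0, \Omega),$$

where $x_i$ holds four binary baseline covariates (BD-II vs BD-I subtype,
female vs male, age ≥ 55 vs < 55, history of rapid cycling) and $\Omega$ is
the full random-effect covariance: its correlations are themselves of
scientific interest (e.g. do people with strong insomnia→mania coupling also
show strong mania→insomnia coupling?).

Trend centring at the grid midpoint keeps $\mu_{ij}$ interpretable as the
mid-study stable level rather than a week-1 intercept. The innovation
covariance is diagonal within person — no same-week residual correlation
between the two processes — matching the model diagram this family of
analyses is built on; the assumption is structural, not estimated, and is a
known limitation below.

### Stationary covariance and individually standardised effects

A stationary person has latent deviation covariance $\Sigma_i$ solving the
discrete Lyapunov equation $\Sigma = \Phi \Sigma \Phi^\top + \Psi$
(`stationaryCovariance()`; closed forms for one and two processes). A raw
cross-lag is not comparable across people whose processes have different
within-person spreads, so effects are standardised *per person*:

$$\phi^*_{jk,i} = \phi_{jk,i}\,\sigma_{ik}/\sigma_{ij},$$

then averaged over people — the "average individually standardised" effect
(`averageStandardisedEffects()`). The averaging is done per posterior draw,
so the reported mean and credible interval propagate estimation uncertainty;
person-draws that fall outside the stationary region are excluded from that
draw's average and counted (a logged exclusion, not a silent truncation;
more than 5% triggers a warning). Standardised inertias equal raw inertias
(the scale cancels), so the interesting output is the cross-lag pair.

## Estimation

`fitDsem()` runs a Metropolis-within-Gibbs sampler (compiled core):

* conjugate normal updates for each person's $(\mu_i, s_i)$ jointly, the lag
  block $\Phi_i$, the fixed effects $\gamma$ and covariate coefficients $B$;
* the lag-block proposal is the conjugate full conditional that ignores the
  initial condition, Metropolis-corrected by the stationary-prior density of
  the latent pre-study deviation; proposals with spectral radius ≥ 1 are
  discarded, keeping every person stationary;
* adaptive random-walk Metropolis on each $\ln \pi_{ij}$ (step size tuned
  during burn-in towards 35% acceptance);
* conjugate inverse-Wishart update for $\Omega$;
* data augmentation: every missing week and each person's pre-study
  deviation are drawn from their full conditionals each sweep, so missing
  data are handled under missing-at-random without deleting rows;
* each person's time-0 deviation is a latent draw initialised from that
  person's stationary distribution, so week 1 contributes likelihood
  instead of being discarded.

Defaults are 2 chains of 2,000 kept iterations after 2,000 burn-in,
convergence declared when every parameter's potential scale reduction is
below 1.1 (a failed check warns and flags the fit, never silently passes).
Identical inputs and seed give bit-identical draws: all randomness flows
through R's RNG, and multi-stage runs expand one master seed via
`stageSeeds()`.

### Priors, and why the $\Omega$ prior matters

Fixed effects get diffuse normals (variance $10^4$; 10 for the log-variance
means, which live on a far smaller scale). For $\Omega$ the default is a
weakly informative inverse-Wishart $IW(\mathrm{diag}(v), d+2)$ whose
diagonal scale $v$ is the variance of crude per-person moment estimates —
the weight of roughly one pseudo-observation. This choice is load-bearing.
The random-effect variances span six orders of magnitude (≈ 21 points² for
depression means, ≈ $10^{-5}$ for slopes), so a unit scale matrix is wildly
informative for several components and, through the inverse-Wishart's
variance–correlation coupling, shrinks weakly identified correlations
towards 0. A near-zero scale matrix is worse: the prior density then behaves
like $|\Omega|^{-(2d+3)/2}$, favouring singular $\Omega$ and pushing weakly
identified correlations towards ±1 (we reproduced this failure with an
independent reduced-model sampler during development). The empirical
diagonal removes both failure modes while leaving the posterior dominated by
the data. A flat $IW(0, -(d+1))$ option is provided
(`omegaPrior = "flat"`); note that flatness over the positive-definite cone
still concentrates individual correlations towards 0 in high dimension.

Covariates enter jointly (all four at once) in conditional models; a
one-at-a-time mode exists because the underlying applied convention is
ambiguous on this point.

## The synthetic-data generator

No raw cohort data are public, so the generator *is* the study system: it
produces panels with exactly the statistical structure the analysis assumes,
plus realistic missingness, and its truth record makes every stage testable.
Defaults emulate a large UK weekly mood-monitoring cohort of adults with
bipolar disorder: 649 participants, 91 weeks (≈ 21 months), covariate
prevalences 0.384 (BD-II), 0.68 (female), 0.40 (age ≥ 55) and 0.30 (rapid
cycling) — the last two are not public and are documented package defaults.

The calibrated fixed effects and individual-mean variances are cohort-level
estimates: means (1.98, 7.33, 3.29) and mean variances (1.96, 21.10, 3.71)
for (hypo)mania, depression and insomnia, inertias (0.40, 0.47, 0.36).
Quantities never printed at cohort level are documented defaults chosen
once for realism and stationarity: log innovation-variance means 1.8
(depression, a within-person shock SD of ≈ 2.5 points) and 0.4 (insomnia and
(hypo)mania, shock SD ≈ 1.2); cross-lag means 0.02; slope mean −0.005
points/week; random-effect SDs 0.15 (inertia), 0.10 (cross-lag), 0.5 (log
innovation variance), 0.005 (slope); `Omega` correlations 0 unless planted
explicitly (e.g. `setSpecCorrelation()`), since the analyses that use them
as ground truth set them per experiment. `calibrateCrossLag()` tunes one raw
cross-lag mean so the generator's *implied* average individually
standardised effect (Monte-Carlo over the random-effect distribution) hits a
requested value.

Person effects are drawn from $N(\gamma + Bx_i, \Omega)$ with rejection of
non-stationary lag matrices (the redraw count is reported; a rejection rate
above 50% errors, since the specified random-effect distribution then
contradicts the model's own stationarity assumption). Series start from each person's stationary distribution. MCAR
missingness removes whole weeks independently; MAR missingness makes the
removal probability a logistic function of the most recent *observed* score
(slope 0.1/point by default, intercept calibrated against the panel's
observed score distribution to hit the target marginal rate) — depending
only on observed values, hence missing-at-random.

What the generator does **not** emulate: bounded, integer, zero-inflated
scores (the default output is continuous; `discretise = TRUE` rounds and
clips, with mild attenuation of dynamics as the documented cost); real
adherence patterns (long gaps, dropout); non-Gaussian shocks; lag intervals
other than one week. Passing recovery tests therefore demonstrates that the
estimation machinery is correct under the model's own assumptions — not that
the model is true of real questionnaire data.

## Numerical choices

* Stationarity margin: spectral radius < 0.999 in the sampler's closed-form
  checks, avoiding near-singular Lyapunov systems.
* Lyapunov solves use exact closed forms (scalar, and Cramer's rule on the
  3×3 vectorised system for bivariate models), verified against the
  Kronecker-product solve to machine precision.
* Eligibility defaults: at least 20 non-missing weeks per modelled outcome
  (the usual intensive-longitudinal-data threshold) and exclusion of
  zero-variance series, which carry no within-person information; both are
  configurable, and every exclusion is logged with a reason.
* Stratified contrasts pair independent posterior draws across strata
  (disjoint participants ⇒ independent fits); the two-tailed p-value is
  $2\min(P(\Delta \ge 0), P(\Delta \le 0))$ capped at 1, so a degenerate
  all-zero difference reads as "no evidence", not significance.
* Ties in the one-tailed p-value follow the strict-inequality convention
  `min(P(>0), P(<0))`.

## Problem sizes used by the test-suite

Unit and property tests run on small panels (15–120 participants, 20–91
weeks, a few hundred MCMC iterations) chosen to exercise every code path
quickly; the end-to-end recovery checks use the full study geometry
(300 participants × 91 weeks, 2 chains × 2,000 kept iterations) where
posterior means must land inside stated tolerance bands around the
generator's calibrated truths. Monte-Carlo oracles (long-series empirical
covariances and regressions) use 2×10⁵–10⁶ steps with tolerances set from
their own sampling error.

## A worked example

```{r example, eval = FALSE}
spec <- defaultDsemSpec(c("dep", "ins"))
sim <- simulatePanel(generatorConfig(spec, n = 120, nWeeks = 91,
                                     missingness = "mar", rate = 0.15,
                                     seed = 7))
el <- applyEligibility(sim$panel)
fit <- fitDsem(el$panel, spec = defaultDsemSpec(c("dep", "ins")), seed = 7)
randomEffectCorrelations(fit)["phi_dep_ins", "phi_ins_dep"]
averageStandardisedEffects(fit)$summary
```

## Known limitations

* One-week lags only: processes operating on faster or slower timescales
  are aliased into the weekly coefficients.
* Diagonal innovation covariance: genuine same-week co-shocks are forced
  into the cross-lags and the between-person correlations.
* MAR is assumed, not testable from the observed data.
* The sampler is specialised to one or two processes; higher-dimensional
  systems would need the general Lyapunov solver and larger blocks.
* Posterior-mean correlations between weakly identified random effects
  remain prior-sensitive at moderate panel sizes; the vignette section on
  the $\Omega$ prior documents the choices and their failure modes.
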