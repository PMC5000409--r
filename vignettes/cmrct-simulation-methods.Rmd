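---
title: "Simulating cluster cmRCTs with risk-correlated treatment refusal"
author: "cmrctsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cluster cmRCTs with risk-correlated treatment refusal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrctsim)
```

## The design being simulated

In a cohort-multiple randomised controlled trial (cmRCT), a standing cohort
— here, patients at high risk of cardiovascular disease (CVD) followed
through routine records — supplies both arms of a trial: a random selection
of patients (in the cluster variant, of whole practices) is *offered* a new
intervention, while the remainder continue usual care without being
contacted. Consent is sought only after randomisation, so patients (and
their clinicians) can refuse the offered intervention, and refusal may well
be correlated with how sick the patient is. Control patients cannot receive
the intervention at all, which makes allocation a one-sided instrument.

This package simulates that design end to end and asks the questions a
trial statistician would ask before running one: how biased are the
intention-to-treat (ITT), per-protocol (PP), and two-stage
instrumental-variable (2SPS, 2SRI) analyses under different refusal
patterns, and what does refusal do to power and sample size?

## The generative model

Each subject $i$ in cluster $k$ carries two normal random effects, an
individual one $\varepsilon_{ik} \sim N(0, \sigma_\varepsilon^2)$ and a
cluster one $U_k \sim N(0, \sigma_u^2)$ shared by all subjects of the
cluster. Both act additively on the log hazards of two latent Weibull
times:

* time to CVD event:
  $h^c_{ik}(t) = \gamma_c t^{\gamma_c-1}/\lambda_c^{\gamma_c}
  \cdot e^{\beta X_{ik} + \varepsilon_{ik} + U_k}$,
* time to death:
  $h^m_{ik}(t) = \gamma_m t^{\gamma_m-1}/\lambda_m^{\gamma_m}
  \cdot e^{\varepsilon_{ik} + U_k}$,

with $X_{ik}$ the treatment actually received. Follow-up is
administratively censored at $T_{max}$; death censors the CVD event, and
because the two times share the random effects, that censoring is
informative. The defaults ($J = 620$ subjects per cluster,
$\gamma_c = 1.2$, $\lambda_c = 36$, $\gamma_m = 1.2$, $\lambda_m = 55$,
$\sigma_\varepsilon^2 = 0.6$, $\sigma_u^2 = 0.2$, $\beta = -0.32$,
$T_{max} = 3$ years) describe a high-CVD-risk primary-care cohort; a second
variance pair $(0.57, 0.27)$ raises the share of cluster-level
heterogeneity and is carried under the metadata tag `icc_label = "0.05"`.
No formula mapping the variance pair to an intra-cluster correlation
coefficient is implemented: no standard scale (latent linear, log-hazard,
or event indicator) reproduces the conventional labels attached to these
pairs, so the variance pairs themselves are treated as the primitive
quantities.

The counterfactual 10-year risk of a subject,
$r_{ik} = 1 - \exp\{-(10/\lambda_c)^{\gamma_c}
e^{\varepsilon_{ik}+U_k}\}$, orders the cohort from healthiest to sickest
and is the handle through which refusal is made informative.

A note on calibration: under the default variances, the Monte-Carlo mean
and standard deviation of $r_{ik}$ are about 24% and 18%, and the Pearson
correlation between the two latent times is about 0.38. These are the
values the model as specified actually produces (the package's acceptance
checks recompute them); reports of this design sometimes quote a
lower risk dispersion for nominally identical parameters, which would
require a much smaller total random-effect variance (roughly 0.25–0.5
rather than 0.8) and cannot be reproduced from the model above. We keep
the model faithful to its stated parameters rather than to any quoted
summary. One consequence worth keeping in mind throughout: the wider the
risk distribution, the stronger every risk–refusal correlation mechanism
becomes, so correlation-driven biases here are on the strong side.

## Refusal: rank-linear probabilities

Mean patient refusal $p$ and clinician refusal $q$ are spread over
individuals by ranking the whole cohort on $r_{ik}$ and interpolating
linearly between a lower and upper limit $(LL, UL)$ chosen by tier:
$(p,p)$, $(2p/3, 4p/3)$, $(p/3, 5p/3)$ or $(0, 2p)$ for zero, low, medium
and high correlation. A *positive* sign gives the sickest patients the
highest refusal probability; a *negative* sign reverses the traversal.
Because every tier is symmetric about $p$, the cohort mean is exact by
construction. Two choices here were genuinely open and are resolved as
follows:

* The direction labels are implemented as ascending vs descending
  traversal of the $LL \to UL$ grid over the risk ranking — the only
  mechanism consistent with rank-linear assignment.
* Probabilities are assigned over the whole cohort before randomisation,
  not per cluster; cluster-level heterogeneity in refusal then arises
  naturally through $U_k$. Patient and clinician probabilities use the
  same risk ordering, so both being tiered makes them mutually correlated
  through risk — nothing suggests they should be independent.
* Rank ties are impossible with continuous random effects but can occur
  under degenerate variances; they are broken by a seeded uniform jitter
  so assignment stays deterministic given the seed.

A trial is then one pass of: 4:1 cluster randomisation (`round(K/5)`
intervention clusters, never fewer than one — the closest integer to the
ratio), uptake $X_{ik} = \min\{\text{Bern}(1-p_{ik}),
\text{Bern}(1-q_{ik})\}$ for offered subjects and $X_{ik}=0$ otherwise,
then the two Weibull times by inverse-CDF sampling (one uniform per time,
so the same seed maps monotonically to times, which also makes
proportional-hazards monotonicity testable draw by draw). Latent times are
kept in the trial table for diagnostics but no estimator sees them.

## Analysis methods

All four methods are Cox proportional-hazards fits on the observed
$\{Y_{ik}, 1-C_{ik}\}$, differing in the treatment covariate:

* **ITT**: allocation $Z$. Refusal dilutes the estimate towards zero by
  roughly the acceptance rate.
* **PP**: received treatment $X$, with intervention-arm refusers dropped.
  Selection on risk-correlated refusal biases this, in the direction of
  whichever tail of the risk distribution remains treated.
* **2SPS**: the first stage regresses $X$ on $Z$ by least squares — with a
  binary one-sided instrument this saturates to group means, so the fitted
  value is $\hat a Z$ with $\hat a$ the intervention-arm acceptance rate —
  and the second stage uses the fitted value. Since the covariate is a
  rescaling of $Z$, the 2SPS coefficient is *exactly* the ITT coefficient
  divided by $\hat a$, and its Wald p-value equals ITT's: the two methods
  share statistical power by construction. (A logistic first stage would
  be degenerate with $X \equiv 0$ in controls, which is why the linear
  stage is the right one here.)
* **2SRI**: second stage on $X$ plus the first-stage residual; the
  residual absorbs the association between uptake and risk. With full
  compliance the residual column is identically zero and is dropped (the
  collinearity threshold is a residual variance below $10^{-12}$), reducing
  2SRI to the fit on $X$.

Clustering is handled three ways, selectable everywhere: a *marginal*
model with cluster-grouped sandwich variance (population-averaged hazard
ratio), a *lognormal frailty* model — a normal random intercept on the
log-hazard scale, matching the generator, fitted by penalised partial
likelihood — and a deliberately misspecified *gamma frailty* model. Fits
go through `survival::coxph()` with Breslow ties (event times are
continuous, so ties have measure zero; the choice is switchable). The
penalised fits get generous inner/outer iteration limits, and if the
sparse frailty algorithm's outer search over the variance diverges — which
happens in a few percent of replicates at 25 clusters — the fit is retried
with the dense parameterisation, which in our experience always converges;
a replicate that still fails, or in which an arm has no events, is
recorded as non-converged, excluded from summaries with a count, and a
scenario with more than 20% such replicates is flagged invalid. All
p-values are naive Wald tests (the power engine uses them); for the
two-stage methods, whose naive second-stage standard errors ignore
first-stage noise, a nonparametric bootstrap that resamples *clusters* —
the randomisation unit, preserving the dependence structure — is available
with a default of 200 resamples.

Two subtleties worth naming. First, frailty models return conditional
(within-cluster) hazard ratios while the marginal model returns
population-averaged ones; at these variances the difference is small but
systematic (non-collapsibility). Second, the *individual* random effect is
not modelled by any of the three (it would not be identifiable); its
presence attenuates both the estimated cluster-frailty variance and, over
follow-up, the observable hazard ratio. This is why the frailty-variance
recovery check in the test suite generates data with
$\sigma_\varepsilon^2 = 0$: only then are the data exactly a shared-frailty
Cox model and $\hat\theta \approx \sigma_u^2$ a clean self-consistency
check.

## The replication engine and its summaries

`run_scenario()` draws a fresh cohort per replicate (the random effects,
risks and refusal probabilities are part of what varies), simulates one
trial, applies the requested methods, and records estimate and p-value.
Summaries per method: mean estimate $\bar\beta$, percentage bias
$100(\bar\beta - \beta)/\beta$, empirical SE (the SD of replicate
estimates), the SE of the mean (empirical SE divided by $\sqrt{n}$ — the
divisor is the square root of the replicate count, the only reading under
which the accompanying confidence-interval formula gives non-degenerate
intervals), a 95% CI for the percentage bias, and power as the fraction of
p-values below $\alpha$. Reproducibility is by a two-level seed scheme:
one base seed yields one sub-seed per replicate (all below $2^{31}$), and
each replicate consumes its stream in a fixed order; the same base seed
reproduces a scenario bitwise, and `run_grid()` extends this to scenario
grids with resume-from-disk support and a JSON manifest.

## Simulation-based sample size

There is no usable closed-form sample-size formula for cluster-randomised,
informatively censored survival data, so `find_sample_size()` searches by
simulation: for candidate cluster counts $K$ (cohort size $N = KJ$, always
a multiple of the cluster size), it simulates trials with *non-informative*
refusal at an assumed rate (zero-tier Bernoulli refusal — recruitment
method 1 is the search at rate zero, method 2 at the anticipated rate),
analyses them by ITT with the lognormal-frailty model (the headline
model; switchable), and returns the smallest $K$ whose power reaches the
target (0.8 at $\alpha = 0.05$ by default). The search doubles $K$ to
bracket the target and then bisects; all candidates share one fixed set of
replicate seeds (common random numbers), which makes the estimated power
curve effectively monotone in $K$ and stabilises the minimality of the
result against Monte-Carlo noise at the boundary. `update_sample_size()`
re-runs the search at a refusal rate observed mid-trial — the mechanism
for keeping a trial powered as refusal information accrues.

Because power is granular in whole clusters and the search stops at the
first candidate at or above target, the realised power at $K^\star$ sits
slightly above 0.8 — around 0.83 at the default design — and declines with
refusal under recruitment method 1 while staying near target under
method 2.

## Problem sizes and numerical choices

The package's own checks run at what we consider desk scale, chosen once:

* Calibration quantities (risk moments, latent-time correlation, relative
  risk reduction) use $4 \times 10^5$–$10^6$ draws; their Monte-Carlo
  error is negligible at that size.
* Bias scenarios run at $K = 25$ clusters of 620. Percentage bias is
  insensitive to the number of clusters (it shifts the variance, not the
  mean, of the estimator), which is what makes a reduced cluster count
  legitimate for bias work; the acceptance script uses 200 replicates per
  scenario (500 in the high-refusal negative-correlation corner), and the
  test suite a further-reduced 100–150 replicates. At these sizes the SE
  of a percentage-bias estimate is 4–8 percentage points, so test
  tolerances are built from each run's own empirical SE rather than fixed
  numbers.
* The sample-size check searches with 50 replicates per candidate under
  common random numbers and re-estimates the realised power at the
  returned $K^\star$ with 150 fresh replicates.

Other numerical choices: Weibull sampling is by inversion (no rejection);
the Weibull convention is fixed to $S(t) = \exp\{-(t/\lambda)^\gamma\}$
with the linear predictor entering the scale as
$\lambda e^{-\eta/\gamma}$, algebraically identical to the hazard form
above (a unit test asserts the sampler against the analytic survivor
function so the two presentations cannot drift apart); frailty fits
converge on relative change in penalised likelihood under `coxph`'s
control settings with the iteration limits raised to 50 inner / 30 outer.

## What passing tests do and do not show

The generator emulates a stylised cohort: constant cluster size, exactly
two normal random effects, no covariates, no staggered entry, no loss to
follow-up other than death, homogeneous treatment effect, and refusal
that is a deterministic rank function of true risk plus Bernoulli noise.
Real cohorts have none of these simplifications, and with a heterogeneous
treatment effect the IV estimand would change character entirely
(complier-average effects are out of scope here). Conclusions from this
simulator are therefore about the *mechanics* of refusal bias and its
correction — the direction and rough size of ITT dilution, PP selection
bias, and the behaviour of 2SPS/2SRI under informative refusal — not
forecasts for any particular trial. Within that scope, two robust
qualitative findings reproduce here: ITT bias grows with refusal and with
the strength of risk–refusal correlation, and 2SRI is the least biased
method on average, with both IV methods overshooting when refusal is high
and strongly correlated with risk.
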