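# cmrctsim

Simulation machinery for the **cluster cohort-multiple randomised
controlled trial (cmRCT)** design with risk-correlated treatment refusal.

In a cmRCT, a standing cohort — here, patients at high risk of
cardiovascular disease (CVD) followed through routine records — supplies
both arms of a trial: a random 1-in-5 selection of clusters (GP practices)
is *offered* a new intervention, the rest continue usual care without
being contacted. Because consent is sought after randomisation, patients
and clinicians can refuse the offered intervention, and sicker patients
may refuse more (or less) often than healthier ones. This package
quantifies what that does to a trial: how biased each standard analysis is
and how much power the trial loses, and how large the trial must be to
survive it. It is aimed at trial statisticians and methodologists
evaluating the feasibility of cluster cmRCTs.

## The model

Subject *i* in cluster *k* carries normal random effects
ε<sub>ik</sub> ~ N(0, σ²<sub>ε</sub>) and U<sub>k</sub> ~ N(0, σ²<sub>u</sub>)
(shared within cluster), acting on the log hazards of two latent Weibull
times:

* CVD event: h<sup>c</sup><sub>ik</sub>(t) = γ<sub>c</sub> t<sup>γ<sub>c</sub>−1</sup>/λ<sub>c</sub><sup>γ<sub>c</sub></sup> · e<sup>βX<sub>ik</sub> + ε<sub>ik</sub> + U<sub>k</sub></sup>
* death: h<sup>m</sup><sub>ik</sub>(t) = γ<sub>m</sub> t<sup>γ<sub>m</sub>−1</sup>/λ<sub>m</sub><sup>γ<sub>m</sub></sup> · e<sup>ε<sub>ik</sub> + U<sub>k</sub></sup>

Observed data per subject are Y = min(T<sup>c</sup>, T<sup>m</sup>, T<sub>max</sub>)
and the censoring indicator C = I(T<sup>c</sup> ≥ min(T<sup>m</sup>, T<sub>max</sub>)):
death and the 3-year administrative horizon censor the event, informatively,
since the times share the random effects. Refusal probabilities are spread
linearly over the cohort's 10-year-risk ranking between tier-specific
limits ((p,p), (2p/3,4p/3), (p/3,5p/3) or (0,2p) for zero/low/medium/high
correlation, traversed in either direction), so the mean refusal is exact
and the risk–refusal correlation is controlled by the tier width.

Four analyses of each simulated trial, each on a marginal (robust),
lognormal-frailty, or gamma-frailty Cox model:

| method | covariate | behaviour under refusal |
|---|---|---|
| ITT  | allocation Z | diluted towards zero |
| PP   | received X, refusers dropped | selection bias with correlated refusal |
| 2SPS | first-stage fitted value (= ITT ÷ acceptance rate) | removes dilution |
| 2SRI | received X + first-stage residual | least biased on average |

`run_scenario()`/`run_grid()` replicate trials and report mean estimate,
percentage bias (100·(mean − β)/β) with CI, empirical SE and power;
`find_sample_size()` finds the smallest cluster count reaching 80% power
by simulation, with (`assumed_refusal > 0`, recruitment method 2) or
without (method 1) refusal factored in.

## Worked example

```r
library(cmrctsim)
params <- cohort_params()            # J = 620, K = 25, beta = -0.32, ...
spec   <- refusal_spec(p = 0.2, tier_p = "high", sign_p = "negative")

cohort <- simulate_cohort(params, spec, seed = 2024)
refusal_risk_correlation(cohort)
#> [1] -0.908

trial <- simulate_trial(cohort, params, seed = 2025)
with(trial, table(z, x))
#>    x
#> z       0     1
#>   0 12400     0
#>   1   552  2548

estimate_itt(trial, model = "lognormal")
#> ITT estimate: log HR = -0.0472 (HR 0.954), naive SE 0.2212, p = 0.831
#>   n used: 15500

res <- run_scenario(params, spec, reps = 100,
                    methods = c("itt", "pp", "2sps", "2sri"),
                    model = "lognormal", base_seed = 42)
res
#> cmRCT scenario: p = 0.2 (high, negative), q = 0, lognormal model, 100 reps
#>  method mean_beta pct_bias pct_bias_lo pct_bias_hi emp_se power n_converged
#>     ITT   -0.2437 -23.8312      -36.86      -10.80 0.2128  0.14         100
#>      PP   -0.1960 -38.7391      -51.68      -25.80 0.2113  0.10         100
#>    2SPS   -0.3111  -2.7846      -19.43       13.87 0.2718  0.14         100
#>    2SRI   -0.3224   0.7428      -16.01       17.49 0.2735  0.16         100
```

Reading: one in five intervention-arm patients refuses, preferentially the
low-risk ones (`sign = "negative"`, realised correlation −0.91). Over 100
replicated trials, ITT underestimates the log hazard ratio by ~24%
(dilution) and per-protocol by ~39% (selection), while the two-stage IV
estimators land within a few percent of the true β = −0.32 — at the price
of a larger empirical SE. Power is low here because 25 clusters is a
bias-study size, not a powered design; `find_sample_size(params)` reports
that ~109 clusters are needed for 80% design power at zero refusal.

A thin command-line front end over the same functions is installed at
`inst/scripts/cmrct.R` (subcommands `simulate`, `grid`, `samplesize`,
`report`).

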