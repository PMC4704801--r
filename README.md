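# dfmpanel

Dynamic factor models for longitudinal panels with **many subjects and
short, possibly unequally spaced visit series** — the shape of data
produced by large observational studies of cognitive ageing, where a
battery of p neuropsychological tests is administered to n subjects at a
handful of roughly annual visits and the goal is a single comparable
latent trait (e.g. underlying cognition) per subject-visit.

## The model

For subject *i* at visit time *t*:

    y_it = f u_it + e_it,        e_it ~ N(0, diag d)      (observation)
    u_i,t+tau = u_it + eta_it,   eta_it ~ N(0, tau)       (transition)

A single latent factor per subject follows a continuous-time random walk
whose innovation variance equals the elapsed time `tau` between visits;
the loadings `f` and idiosyncratic variances `d` are shared across
subjects, which identifies the model and makes factor scores comparable
between people.  Missing test scores and unequal spacing are handled
exactly by the Kalman filter.  Estimation uses a two-cycle ECME
algorithm: closed-form factor-analysis EM updates of the variances
(cycle 1) alternate with quasi-Newton maximisation of the exact Kalman
prediction-error log-likelihood over the loadings (cycle 2), with a
conditional-maximisation fallback on the variances at convergence.
Subjects are conditionally independent, so the filter runs as n scalar
recursions with O(p) visit updates (compiled code) instead of one
O((np)^3) stacked filter — which is what makes n in the hundreds
tractable.

The package also provides:

* `fit_cfm()` — the non-dynamic confirmatory comparator (observation
  equation only, factor i.i.d. across visits, regression scores), to
  quantify the value of temporal information;
* `simulate_panel()` / `simulate_two_group_panel()` — synthetic panel
  generators with known latent paths, including matched case–control
  pairs with a latent rate-of-change contrast;
* `trace_statistic()` and `run_grid()` — latent-recovery evaluation
  (multivariate R² of true on estimated factors) and the Monte Carlo
  experiment driver;
* `residual_diagnostics()` / `diagnose_fit()` — normality and lag-1
  autocorrelation checks of standardised one-step prediction errors;
* `fit_slope_contrast()`, `bootstrap_power()`,
  `required_sample_size()` — matched-pair bootstrap power analysis for
  group differences in the annual rate of latent change;
* a thin command-line entry point (`inst/exec/dfmpanel`) with
  `simulate`, `fit`, `table1`, `power` and `diagnose` subcommands.

## Worked example

```r
library(dfmpanel)

sim <- simulate_panel(n = 50, p = 5, T_ = 7, seed = 1)   # known truth
fit <- fit_dfm(sim$panel, init_state = init_policy("prior"))
print(fit)
#> DFM fit: p = 5, log-likelihood = -1639.719, iterations = 4, converged = TRUE
#> loadings:  0.1383 0.151 0.2435 0.4065 0.08696
#> variances: 0.6213 1.128 0.4954 0.6114 0.01445

round(rbind(true = sim$loadings, estimated = fit$loadings), 3)
#>            [,1]  [,2]  [,3]  [,4]  [,5]
#> true      0.114 0.160 0.247 0.391 0.087
#> estimated 0.138 0.151 0.244 0.407 0.087

head(extract_scores(fit), 4)     # smoothed latent trait per subject-visit
#>   subject time      score score_var
#> 1     s01    1 -0.6212869 0.4816647
#> 2     s01    2  0.3823563 0.4607688
#> 3     s01    3  0.9334619 0.4576961
#> 4     s01    4  1.1040056 0.4577369
```

The estimated loadings track the generating ones, and the smoothed scores
recover the latent paths: comparing against the simulated truth,

```r
tr  <- trace_statistic(sim$latent$u, fit$scores$score)
cfm <- fit_cfm(sim$panel)
trc <- trace_statistic(sim$latent$u, cfm$scores$score)
sprintf("TR_DFM = %.3f, TR_CFM = %.3f, ratio = %.3f", tr, trc, tr / trc)
#> "TR_DFM = 0.901, TR_CFM = 0.836, ratio = 1.078"
```

i.e. the dynamic model explains 90% of the variability of the true latent
paths on this panel, about 8% more than the non-dynamic comparator, which
ignores the visit ordering.

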