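# trajmix

Group-based trajectory modeling of longitudinal arrest counts across birth
cohorts, for criminologists and life-course researchers working with
accelerated multicohort designs (different cohorts observed over different,
partially overlapping age windows).

## The model

Let `Y_i = (y_i1, ..., y_iT)` be person `i`'s arrest counts at integer ages
`Age_i`. The population is assumed to be a finite mixture of `J` latent
trajectory groups:

```
P(Y_i | Age_i) = Σ_j  π_j(x_i) · Π_t Poisson(y_it ; λ_j(age_it))
λ_j(a)  = exp( β_j' · basis(a) )            cubic polynomial or B-spline in age
π_j(x)  = softmax_j( θ_j' · (1, x) )        multinomial logit, group 1 = reference
```

Counts are conditionally independent Poisson given group membership, each
group has its own age-rate curve `λ_j(a)`, and the membership probabilities
`π_j` may condition on baseline covariates `x` (e.g. a birth-cohort
indicator, sex, parental welfare receipt, self-control). Estimation is by
maximum likelihood: multi-start EM (posterior-weighted Poisson regressions
and a weighted multinomial-logit update) followed by a BFGS polish on the
full likelihood with the analytic score. Around the estimator the package
provides:

* **Model selection** — BIC over a grid of group counts `J` and functional
  forms, with both persons and person-periods as the sample-size convention.
* **Classification diagnostics** — assigned shares, average posterior
  probability of membership (AvePP, adequate above 0.7), odds of correct
  classification.
* **Membership analysis** — covariate odds ratios against the low group
  with Wald tests, average-predicted profile probabilities and contrasts,
  Rubin's-rules pooling across multiply imputed covariate sets.
* **Rates and decomposition** — within-group arrest-rate tables by cohort
  and offense category over a fixed age window, permutation tests for
  cohort contrasts, and a counterfactual decomposition of a cohort rate gap
  into group-composition and within-group-rate components.
* **Synthetic data** — a fully specified multicohort generator
  (`default_cohort_spec()`) emulating four birth cohorts with unbalanced
  windows, three trajectory groups peaking near age 19, cohort- and
  covariate-dependent membership, and group-by-cohort charge mixes, so the
  whole pipeline is testable without access to restricted arrest records.

## Worked example

```r
library(trajmix)

gs  <- default_cohort_spec()
sim <- simulate_panel(gs, 1000, seed = 530)
fit <- fit_trajectories(sim$panel, J = 3, n_starts = 3, seed = 14,
                        em_tol = 1e-6)
fit
#> <traj_fit> J = 3, loglik = -4017.611, BIC(persons) = 8131.931
#>   mean posterior shares: 0.789 / 0.163 / 0.048
#>   converged: TRUE (gradient norm 3.32e-06, 3 start(s))

round(rate(fit$model, 3, c(19, 30)), 2)   # high-group curve at 19 and 30
#> [1] 1.43 0.56

adequacy(fit)
#>        group pi_hat assigned_share avepp    occ adequate
#> group1     1  0.789          0.807 0.961    6.6     TRUE
#> group2     2  0.163          0.145 0.906   49.6     TRUE
#> group3     3  0.048          0.048 0.998 9655.4     TRUE
```

The three rows are the low / medium / high trajectory groups: about
four-fifths of simulated persons are rarely arrested, a sixth follow a
moderate hump-shaped curve peaking near 0.33 expected arrests at age 19,
and ~5% follow a high curve peaking near 1.4. `avepp` well above 0.7 means
the groups are cleanly separable from the count histories alone.

Counterfactual decomposition of a cohort gap from a rate table:

```r
d <- decompose(shares_young = c(0.88, 0.086, 0.037),
               rates_young  = c(0.10, 2.52, 8.07),
               shares_old   = c(0.74, 0.21, 0.049),
               rates_old    = c(0.16, 2.44, 10.88), target_group = 3)
d
#> <traj_decomposition>
#>   actual rates: younger 0.603, older 1.164 (gap 0.561)
#>   rate_swap         0.753 (+24.8% vs younger actual)
#>   composition_swap  0.999 (+65.5% vs younger actual)
#>   targeted          0.707 (+17.2% vs younger actual)
```

Had the younger cohorts carried the older cohorts' group composition at
their own within-group rates, their arrest rate would have been ~66%
higher — group membership shifts dominate the cohort gap, with the high
group's within-rate difference contributing most of the remainder.

The end-to-end pipeline (`run_pipeline(pipeline_config(...))`) chains age
restriction, model selection, diagnostics, membership analysis, rate
tables, the permutation test and the decomposition, writing a versioned
`results.json` plus CSV tables and per-age trajectory-curve points.

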