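# jointpsa

Joint modelling of longitudinal prostate-specific antigen (PSA)
measurements after radiotherapy and time to prostate-cancer recurrence.

Serial PSA is the standard surveillance tool after radiation therapy for
localized prostate cancer, but relating the biomarker to recurrence risk is
statistically delicate: PSA is endogenous, measured with error, observed at
irregular per-patient schedules, and follow-up is right-censored. This
package implements the shared-random-effects joint model for that setting,
for biostatisticians and methodologists who want a tested, self-contained
reference implementation with a matching synthetic-cohort generator.

## The model

A linear mixed sub-model describes each subject's error-free transformed
PSA trajectory,

    y_ij = m_i(t_ij) + e_ij,
    m_i(t) = x_i(t)' beta + b_i0 + b_i1 t,      e_ij ~ N(0, sigma^2),
    (b_i0, b_i1) ~ N(0, D),

with fixed effects for hormone therapy, radiation dose group, time, and
time-by-treatment interactions (transform: log(PSA + 0.1) by default). A
proportional-hazards sub-model ties the recurrence hazard to the current
trajectory value and its slope,

    h_i(t) = h0(t) exp{ gamma' w_i + alpha m_i(t) + alpha_s m_i'(t) },

with baseline covariates w_i (hormone therapy, dose group, t-stage,
Gleason group, age) and a Weibull, piecewise-constant, or B-spline
baseline h0. Estimation is maximum likelihood via an EM algorithm:
pseudo-adaptive 9-node Gauss-Hermite quadrature for the random effects,
Gauss-Legendre quadrature for the cumulative hazard, closed-form M-step
updates for the variance components and quasi-Newton updates for the rest,
with a monotone log-likelihood guarantee. `exp(alpha)` is the relative
risk per one-unit increase in transformed PSA; `exp(alpha_s)` per
one-unit-per-year increase in its slope.

## Worked example

```r
library(jointpsa)

cohort <- generate_cohort(sim_config(n_subjects = 150, seed = 42))
cohort
#> PSA cohort: 150 subjects, 370 PSA measurements
#>   events: 35 (23.3%)
#>   transform: log_shift (shift 0.1)

fit <- em_fit(cohort, compute_se = TRUE, tol_loglik = 1e-6)
fit
#> Joint longitudinal-survival model fit (weibull baseline)
#>   log-likelihood -542.157, AIC 1132.315, 24 parameters
#>   23 EM iterations, converged: TRUE
#>   alpha (current value) -0.1347, alpha_s (slope) -0.7950

tab <- rr_table(fit)
tab[tab$parameter %in% c("stage_3_4", "alpha", "alpha_s"), ]
#>  parameter   coef    se    rr ci_low ci_high p_value
#>  stage_3_4  1.916 0.414 6.796  3.021  15.293   0.000
#>      alpha -0.135 0.219 0.874  0.569   1.342   0.538
#>    alpha_s -0.795 1.012 0.452  0.062   3.281   0.432

kaplan_meier(cohort$subjects$event_time_years, cohort$subjects$event)
#> Kaplan-Meier estimate: 150 subjects, 35 events
#>   median survival: not reached
```

The cohort was simulated with a strong advanced-stage effect (generative
relative risk 5.79) and modest associations (alpha = 0.33, alpha_s =
0.19); at 150 subjects and 35 events the stage effect is recovered clearly
(RR 6.8, CI 3.0-15.3) while the association estimates are individually
noisy (alpha here is -0.13 with standard error 0.22) - single small-cohort
fits say little about associations of this size, which is why the package
ships a replicate-based recovery study (`run_recover()`).

Pipeline helpers mirror a command-line workflow: `run_simulate()`,
`run_fit()` (writes `fit.json`, `rr_table.tsv`, `trace.tsv`), `run_km()`,
`run_compare()` (AIC table across baseline families), `run_recover()`
(replicate recovery report), and a thin shell wrapper at
`inst/exec/jointpsa`.

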