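# Shared fixtures: all cohorts are built in code at test time.

# hand-built two-subject cohort with known numbers
tiny_cohort <- function(transform = transform_spec()) {
  subjects <- data.frame(
    subject_id = c("A", "B"),
    event_time_years = c(1.5, 2.0),
    event = c(1, 0),
    hormone_therapy = c(0, 1),
    dose_group = c("le50", "ge70"),
    stage_group = c("1-2", "3-4"),
    gleason_group = c("2-5", "7"),
    age_years = c(65, 72),
    stringsAsFactors = FALSE)
  observations <- data.frame(
    subject_id = rep(c("A", "B"), each = 3),
    time_years = c(0, 0.5, 1.0, 0, 0.75, 1.5),
    psa_ng_ml = c(8, 5, 3, 12, 7, 4),
    stringsAsFactors = FALSE)
  psa_cohort(subjects, observations, transform)
}

# small simulated cohort from the default generative truth
sim_cohort <- function(n = 60, seed = 42, ...) {
  generate_cohort(sim_config(n_subjects = n, seed = seed, ...))
}

# a null-association generative truth (alpha = alpha_s = 0)
null_generative <- function(scale = 3) {
  jp <- default_generative_params()
  joint_params(jp$longitudinal,
               survival_params(jp$survival$gamma,
                               weibull_hazard(shape = 1.2, scale = scale)),
               alpha = 0, alpha_s = 0)
}

expect_monotone_trace <- function(fit, tol = 1e-6) {
  expect_true(all(diff(fit$trace) >= -tol),
              label = paste("EM log-likelihood trace nondecreasing for fit with",
                            fit$n_iter, "iterations"))
}
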