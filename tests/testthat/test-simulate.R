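test_that("covariate margins are matched in expectation", {
  m <- default_margins()
  stubs <- simulate_covariates(10000, m, seed = 2)
  expect_lt(abs(mean(stubs$stage_group == "3-4") - 0.277), 0.02)
  for (g in names(m$gleason))
    expect_lt(abs(mean(stubs$gleason_group == g) - m$gleason[g]), 0.02)
  expect_equal(median(stubs$age_years), 71, tolerance = 3)
  # degenerate margin puts everyone in one class; n = 1 yields one full row
  m1 <- m; m1$dose <- c("le50" = 1, "51-69" = 0, "ge70" = 0)
  expect_true(all(simulate_covariates(500, m1, seed = 3)$dose_group == "le50"))
  one <- simulate_covariates(1, m, seed = 4)
  expect_equal(nrow(one), 1)
  expect_false(anyNA(one))
  m_bad <- m; m_bad$stage <- c("1-2" = 0.5, "3-4" = 0.2)
  expect_error(simulate_covariates(10, m_bad), "invalid")
})

test_that("trajectory simulation follows the visit schedule and the model", {
  jp <- default_generative_params()
  stub <- simulate_covariates(1, seed = 5)
  # visit count: floor(follow-up / gap) + 1
  tr <- simulate_trajectory(stub, c(0, 0), jp, visit_gap = 0.25,
                            follow_up = 0.87, seed = 6)
  expect_equal(tr$time_years, c(0, 0.25, 0.5, 0.75))
  # noise-free trajectories lie exactly on m_i(t)
  lo0 <- longitudinal_params(jp$longitudinal$beta, jp$longitudinal$D, 1e-300)
  jp0 <- joint_params(lo0, jp$survival, jp$alpha, jp$alpha_s)
  tr0 <- simulate_trajectory(stub, c(0.2, 0.1), jp0, follow_up = 1, seed = 7)
  m <- trajectory_value(lo0, c(0.2, 0.1), stub, tr0$time_years)
  expect_equal(log(tr0$psa_ng_ml + 0.1), m, tolerance = 1e-9)
})

test_that("measurement noise has the configured variance", {
  jp <- default_generative_params()
  stub <- simulate_covariates(1, seed = 8)
  stub$dose_group <- "le50"; stub$hormone_therapy <- 0
  set.seed(9)
  y <- replicate(10000, {
    tr <- simulate_trajectory(stub, c(0, 0), jp, visit_gap = 0.25,
                              follow_up = 0.25)
    log(tr$psa_ng_ml[2] + 0.1)
  })
  expect_equal(var(y), jp$longitudinal$sigma2, tolerance = 0.05 * 0.36)
})

test_that("event-time inversion is exact in the exponential case", {
  jp0 <- null_generative()
  jp0$survival$gamma[] <- 0
  jp0$survival$baseline <- weibull_hazard(1, 1)
  stub <- simulate_covariates(1, seed = 10)
  for (u in c(0.05, 0.3, 0.7, 0.95))
    expect_equal(simulate_event_time(stub, c(0, 0), jp0, u), -log(u),
                 tolerance = 1e-7)
  # monotone: t nonincreasing in u
  us <- seq(0.05, 0.95, by = 0.1)
  ts <- vapply(us, function(u)
    simulate_event_time(stub, c(0, 0), jp0, u), numeric(1))
  expect_true(all(diff(ts) <= 1e-10))
  expect_error(simulate_event_time(stub, c(0, 0), jp0, 0), "u > 0")
})

test_that("generated cohorts are reproducible and respect truncation", {
  cfg <- sim_config(n_subjects = 30, seed = 123)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(sim_config(n_subjects = 30, seed = 123))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1); write_cohort(c2, d2)
  expect_identical(readLines(file.path(d1, "longitudinal.csv")),
                   readLines(file.path(d2, "longitudinal.csv")))
  expect_identical(readLines(file.path(d1, "survival.csv")),
                   readLines(file.path(d2, "survival.csv")))
  et <- c1$subjects$event_time_years[
    match(c1$observations$subject_id, c1$subjects$subject_id)]
  expect_true(all(c1$observations$time_years <= et + 1e-12))
  # a vanishing horizon censors everyone almost immediately with one visit
  c0 <- generate_cohort(sim_config(n_subjects = 15, seed = 5,
                                   censor_horizon = 0.01))
  expect_true(all(c0$subjects$event_time_years <= 0.01 + 1e-9))
  expect_equal(nrow(c0$observations), 15)
})
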