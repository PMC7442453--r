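test_that("design rows encode covariates and interactions as products", {
  co <- tiny_cohort()
  spec <- fixed_effects_spec()
  # subject A: all reference covariates, t = 0
  dm <- build_design(co$subjects[1, ], 0, spec)
  expect_equal(drop(dm$X), c(intercept = 1, hormone_therapy = 0,
                             dose_51_69 = 0, dose_ge70 = 0, time = 0,
                             time_hormone = 0, time_dose_51_69 = 0,
                             time_dose_ge70 = 0),
               ignore_attr = TRUE)
  expect_equal(drop(dm$Z), c(1, 0), ignore_attr = TRUE)
  # subject B: hormone = 1, dose ge70, t = 2
  dm <- build_design(co$subjects[2, ], 2, spec)
  x <- drop(dm$X)
  names(x) <- spec$terms
  expect_equal(unname(x[c("time_hormone", "time_dose_ge70")]), c(2, 2))
  expect_equal(unname(x["time_dose_51_69"]), 0)
})

test_that("X beta matches a term-by-term scalar accumulation", {
  co <- sim_cohort(n = 8, seed = 11)
  spec <- fixed_effects_spec(include_quadratic_time = TRUE)
  set.seed(5)
  beta <- rnorm(length(spec$terms))
  for (i in c(2, 5)) {
    s <- co$subjects[i, ]
    t <- c(0.3, 1.7)
    X <- build_design(s, t, spec)$X
    h <- as.numeric(s$hormone_therapy)
    d2 <- as.numeric(s$dose_group == "51-69")
    d3 <- as.numeric(s$dose_group == "ge70")
    hand <- beta[1] + beta[2] * h + beta[3] * d2 + beta[4] * d3 +
      beta[5] * t + beta[6] * t^2 + beta[7] * t * h + beta[8] * t * d2 +
      beta[9] * t * d3
    expect_equal(drop(X %*% beta), hand, tolerance = 1e-12)
  }
})

test_that("build_design is permutation-equivariant in times", {
  s <- tiny_cohort()$subjects[2, ]
  t <- c(0.2, 1.4, 0.9, 0)
  perm <- c(3, 1, 4, 2)
  a <- build_design(s, t, fixed_effects_spec())
  b <- build_design(s, t[perm], fixed_effects_spec())
  expect_equal(a$X[perm, ], b$X, ignore_attr = TRUE)
  expect_equal(a$Z[perm, ], b$Z, ignore_attr = TRUE)
})

test_that("trajectory value is the published linear predictor", {
  co <- tiny_cohort()
  jp <- default_generative_params()
  lo <- jp$longitudinal
  # reference covariates, b = 0, t = 0 -> intercept
  expect_equal(trajectory_value(lo, c(0, 0), co$subjects[1, ], 0),
               lo$beta[["intercept"]])
  # intercept 3.67 + time (-1.48) at t = 1 -> 2.19
  expect_equal(trajectory_value(lo, c(0, 0), co$subjects[1, ], 1),
               3.67 - 1.48)
  # beta = 0: pure random part a + c t
  lo0 <- longitudinal_params(rep(0, 8), lo$D, lo$sigma2)
  expect_equal(trajectory_value(lo0, c(0.7, -0.3), co$subjects[1, ], c(0, 2)),
               c(0.7, 0.7 - 0.6))
  expect_error(trajectory_value(lo, c(0, 0, 0), co$subjects[1, ], 1),
               "random-effects")
})

test_that("trajectory slope is the analytic time derivative", {
  co <- tiny_cohort()
  jp <- default_generative_params()
  lo <- jp$longitudinal
  s <- co$subjects[2, ]
  b <- c(0.4, -0.2)
  # linear-time spec: slope constant in t
  sl <- trajectory_slope(lo, b, s, c(0.1, 1.3, 2.9))
  expect_equal(sl[1], sl[2])
  expect_equal(sl[2], sl[3])
  # quadratic spec: beta_t + 2 beta_t2 t + c, checked by finite differences
  spec2 <- fixed_effects_spec(include_quadratic_time = TRUE)
  set.seed(8)
  beta2 <- rnorm(9)
  lo2 <- longitudinal_params(beta2, lo$D, lo$sigma2)
  for (t in c(0.2, 1, 2.5)) {
    h <- 1e-6
    fd <- (trajectory_value(lo2, b, s, t + h, spec2) -
             trajectory_value(lo2, b, s, t - h, spec2)) / (2 * h)
    expect_equal(trajectory_slope(lo2, b, s, t, spec2), fd,
                 tolerance = 1e-6)
  }
})
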