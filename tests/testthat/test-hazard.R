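test_that("weibull hazard: exponential special case and closed forms", {
  b <- weibull_hazard(shape = 1, scale = 2)
  expect_equal(baseline_hazard(b, c(0.3, 1, 7)), rep(0.5, 3))
  expect_equal(cumulative_hazard(weibull_hazard(2, 1), 3), 9)
  expect_equal(cumulative_hazard(b, 0), 0)
  expect_error(baseline_hazard(b, 0), "> 0")
})

test_that("piecewise hazard uses right-open intervals and closed-form H0", {
  b <- piecewise_hazard(c(0, 1), c(0.1, 0.3))
  expect_equal(baseline_hazard(b, 1.0), 0.3)  # boundary belongs to the right
  expect_equal(baseline_hazard(b, 0.999), 0.1)
  expect_equal(cumulative_hazard(b, 2.5), 0.1 * 1 + 0.3 * 1.5)
  expect_equal(cumulative_hazard(b, 0.4), 0.04)
})

test_that("every family satisfies the hazard/cumulative-hazard contract", {
  fams <- list(
    weibull_hazard(shape = 1.5, scale = 3),
    piecewise_hazard(c(0, 0.5, 1, 2), c(0.2, 0.4, 0.1, 0.3)),
    bspline_hazard(knots = c(0.5, 1, 1.5), coef = c(-2, -1, -0.5, -1.5,
                                                    -0.8, -1.2, -2),
                   boundary = c(0, 3)))
  grid <- seq(0.05, 2.8, length.out = 40)
  for (b in fams) {
    H <- cumulative_hazard(b, grid)
    expect_true(all(diff(H) > 0))
    expect_true(all(exp(-H) > 0 & exp(-H) <= 1))
    # numeric derivative of H0 equals h0 (skip piecewise jump points)
    h <- 1e-6
    num <- (cumulative_hazard(b, grid + h) -
              cumulative_hazard(b, grid - h)) / (2 * h)
    jump <- if (inherits(b, "piecewise_hazard"))
      sapply(grid, function(t) min(abs(t - b$breaks))) < 1e-5 else FALSE
    expect_equal(num[!jump], baseline_hazard(b, grid)[!jump],
                 tolerance = 1e-5)
  }
})

test_that("bspline cumulative hazard matches composite-Simpson integration", {
  b <- bspline_hazard(knots = c(0.5, 1, 1.5),
                      coef = c(-2, -1, -0.5, -1.5, -0.8, -1.2, -2),
                      boundary = c(0, 3))
  for (t in c(0.7, 1.9, 2.9)) {
    m <- 10000
    s <- seq(0, t, length.out = m + 1)
    f <- baseline_hazard(b, pmax(s, 1e-12))
    simpson <- (t / m) / 3 * sum(f * c(1, rep(c(4, 2), length.out = m - 1), 1))
    expect_equal(cumulative_hazard(b, t), simpson, tolerance = 1e-6)
  }
})

test_that("subject hazard is baseline times exp of the linear predictor", {
  co <- tiny_cohort()
  jp <- default_generative_params()
  s <- co$subjects[1, ]
  # null association and gamma = 0 reduces to the baseline
  jp0 <- joint_params(jp$longitudinal,
                      survival_params(rep(0, 8), weibull_hazard(1.3, 2)),
                      alpha = 0, alpha_s = 0)
  tt <- c(0.4, 1.1)
  expect_equal(subject_hazard(jp0, c(0, 0), s, tt),
               baseline_hazard(jp0$survival$baseline, tt))
  # single-factor check: alpha = 0.33 with m = 1 multiplies hazard by e^0.33
  lo1 <- longitudinal_params(c(1, rep(0, 7)), jp$longitudinal$D,
                             jp$longitudinal$sigma2)
  jpa <- joint_params(lo1, survival_params(rep(0, 8), weibull_hazard(1, 1)),
                      alpha = 0.33, alpha_s = 0)
  expect_equal(subject_hazard(jpa, c(0, 0), s, 1), exp(0.33),
               tolerance = 1e-12)
  # log-linearity in (alpha, m) for random parameter draws
  set.seed(21)
  for (r in 1:5) {
    a <- rnorm(1); b_i <- rnorm(2); t <- runif(1, 0.1, 2)
    jpr <- joint_params(jp$longitudinal, jp$survival, alpha = a, alpha_s = 0)
    jp00 <- joint_params(jp$longitudinal, jp$survival, alpha = 0, alpha_s = 0)
    m <- trajectory_value(jp$longitudinal, b_i, s, t)
    expect_equal(log(subject_hazard(jpr, b_i, s, t)) -
                   log(subject_hazard(jp00, b_i, s, t)), a * m,
                 tolerance = 1e-10)
  }
})

test_that("Kaplan-Meier matches hand-computed product limits", {
  # no censoring: empirical survival
  km <- kaplan_meier(1:4, rep(1, 4))
  expect_equal(km$table$survival, c(3, 2, 1, 0) / 4)
  # censored pattern {1, 2+, 3, 4+, 5}
  km <- kaplan_meier(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
  ev <- km$table[km$table$events > 0, ]
  expect_equal(ev$survival, c(4 / 5, 4 / 5 * 2 / 3, 0), tolerance = 1e-12)
  # all censored: flat survival, median not reached
  km <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km$table$survival == 1))
  expect_true(is.na(km$median))
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("Greenwood bands are valid and the median lies inside its CI", {
  set.seed(31)
  tt <- rexp(120, 0.4); ev <- rbinom(120, 1, 0.7)
  km <- kaplan_meier(tt, ev)
  with(km$table[km$table$events > 0 & km$table$survival > 0, ], {
    expect_true(all(ci_low <= survival + 1e-12))
    expect_true(all(ci_high >= survival - 1e-12))
  })
  expect_true(km$median >= km$median_ci["lower"] - 1e-12)
  expect_true(km$median <= km$median_ci["upper"] + 1e-12)
  # median definition: earliest time with S <= 0.5
  s <- km$table
  expect_equal(km$median, min(s$time[s$survival <= 0.5]))
})
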