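# Independent scalar/vectorized re-implementations of the conditional
# likelihood are used as oracles throughout this file: they share nothing
# with the package's matrix engine beyond the model formulas.

test_that("conditional log-likelihood matches closed forms in special cases", {
  co <- tiny_cohort()
  s <- co$subjects[2, ]   # censored at T = 2
  obs <- co$observations[co$observations$subject_id == "B", ]
  jp <- default_generative_params()
  # alpha = alpha_s = gamma = 0, Weibull k=1, lambda=1: survival part = -T
  jp0 <- joint_params(jp$longitudinal,
                      survival_params(rep(0, 8), weibull_hazard(1, 1)),
                      alpha = 0, alpha_s = 0)
  b <- c(0.3, -0.1)
  m <- trajectory_value(jp0$longitudinal, b, s, obs$time_years)
  gauss <- sum(dnorm(obs$psa_star, m, 0.6, log = TRUE))
  expect_equal(subject_loglik_given_b(jp0, s, obs, b), gauss - 2,
               tolerance = 1e-10)
  # event at T with constant hazard c: survival part = log c - c T
  s1 <- co$subjects[1, ]  # event at T = 1.5
  obs1 <- co$observations[co$observations$subject_id == "A", ]
  cc <- 0.7
  jpc <- joint_params(jp$longitudinal,
                      survival_params(rep(0, 8), weibull_hazard(1, 1 / cc)),
                      alpha = 0, alpha_s = 0)
  m1 <- trajectory_value(jpc$longitudinal, b, s1, obs1$time_years)
  gauss1 <- sum(dnorm(obs1$psa_star, m1, 0.6, log = TRUE))
  expect_equal(subject_loglik_given_b(jpc, s1, obs1, b),
               gauss1 + log(cc) - cc * 1.5, tolerance = 1e-10)
})

test_that("Gauss-Legendre cumulative-hazard term matches adaptive quadrature", {
  co <- tiny_cohort()
  jp <- default_generative_params()
  for (i in 1:2) {
    s <- co$subjects[i, ]
    s$event <- 0   # so the survival term is exactly -Lambda_i(T_i)
    obs <- co$observations[co$observations$subject_id == s$subject_id, ]
    b <- c(0.5, -0.4)
    m <- trajectory_value(jp$longitudinal, b, s, obs$time_years)
    gauss <- sum(dnorm(obs$psa_star, m, sqrt(jp$longitudinal$sigma2),
                       log = TRUE))
    lam_pkg <- gauss - subject_loglik_given_b(jp, s, obs, b)
    adapt <- integrate(function(t) subject_hazard(jp, b, s, t),
                       0, s$event_time_years,
                       rel.tol = 1e-12, abs.tol = 0)$value
    expect_equal(lam_pkg, adapt, tolerance = 1e-8)
  }
})

test_that("GH marginal likelihood matches dense-grid brute-force integration", {
  co3 <- local({
    co <- sim_cohort(n = 3, seed = 77)
    co
  })
  jp <- default_generative_params()
  spec <- fixed_effects_spec(); re <- random_effects_spec()
  lo <- jp$longitudinal
  # independent brute force: Simpson over [-6 sd1, 6 sd1] x [-6 sd2, 6 sd2]
  sd1 <- sqrt(lo$D[1, 1]); sd2 <- sqrt(lo$D[2, 2])
  m <- 200
  g1 <- seq(-6 * sd1, 6 * sd1, length.out = m + 1)
  g2 <- seq(-6 * sd2, 6 * sd2, length.out = m + 1)
  wsimp <- c(1, rep(c(4, 2), length.out = m - 1), 1)
  W2 <- outer(wsimp, wsimp) * (diff(g1)[1] / 3) * (diff(g2)[1] / 3)
  Dinv <- solve(lo$D)
  brute <- 0
  rule <- quadrature_rule()
  for (i in 1:3) {
    s <- co3$subjects[i, ]
    obs <- co3$observations[co3$observations$subject_id == s$subject_id, ]
    dm <- build_design(s, obs$time_years, spec, re)
    fixed <- drop(dm$X %*% lo$beta)
    w <- drop(jointpsa:::survival_design(s))
    eta_w <- sum(jp$survival$gamma * w)
    Tt <- s$event_time_years
    xT <- drop(build_design(s, Tt, spec, re)$X %*% lo$beta)
    dxT <- drop(build_design(s, Tt, spec, re, derivative = TRUE)$X %*% lo$beta)
    sgl <- Tt / 2 * (rule$gl_x + 1); vgl <- Tt / 2 * rule$gl_w
    xs <- drop(build_design(s, sgl, spec, re)$X %*% lo$beta)
    dxs <- drop(build_design(s, sgl, spec, re, derivative = TRUE)$X %*% lo$beta)
    lh0s <- log(1.2 / jp$survival$baseline$scale) +
      0.2 * (log(sgl) - log(jp$survival$baseline$scale))
    lh0T <- log(1.2 / jp$survival$baseline$scale) +
      0.2 * (log(Tt) - log(jp$survival$baseline$scale))
    val <- matrix(0, m + 1, m + 1)
    for (a in seq_len(m + 1)) {
      b1 <- g1[a]
      mu_obs <- outer(fixed + b1, rep(1, m + 1)) + outer(obs$time_years, g2)
      gauss <- colSums(dnorm(matrix(obs$psa_star, nrow(obs), m + 1), mu_obs,
                             sqrt(lo$sigma2), log = TRUE))
      mT <- xT + b1 + g2 * Tt
      dmT <- dxT + g2
      lam <- colSums(vgl * exp(lh0s + eta_w +
                                 jp$alpha * (outer(xs + b1, rep(1, m + 1)) +
                                               outer(sgl, g2)) +
                                 jp$alpha_s * (outer(dxs, rep(1, m + 1)) +
                                                 matrix(g2, length(sgl),
                                                        m + 1, byrow = TRUE))))
      surv <- s$event * (lh0T + eta_w + jp$alpha * mT + jp$alpha_s * dmT) - lam
      prior <- -log(2 * pi) - 0.5 * log(det(lo$D)) -
        0.5 * (Dinv[1, 1] * b1^2 + 2 * Dinv[1, 2] * b1 * g2 +
                 Dinv[2, 2] * g2^2)
      val[a, ] <- exp(gauss + surv + prior)
    }
    brute <- brute + log(sum(W2 * val))
  }
  expect_equal(marginal_loglik(jp, co3), brute, tolerance = 1e-4)
})

test_that("marginal likelihood is insensitive to doubling the GH order", {
  co <- sim_cohort(n = 25, seed = 19)
  jp <- default_generative_params()
  l9 <- marginal_loglik(jp, co, quadrature_rule(gh_nodes = 9))
  l15 <- marginal_loglik(jp, co, quadrature_rule(gh_nodes = 15))
  expect_equal(l9, l15, tolerance = 1e-4)
})

test_that("null-association joint likelihood factorizes into LMM + Weibull PH", {
  # identity at fixed parameters on a 5-subject fixture
  co <- sim_cohort(n = 5, seed = 122)
  jp <- default_generative_params()
  jp0 <- joint_params(jp$longitudinal, jp$survival, alpha = 0, alpha_s = 0)
  expect_equal(marginal_loglik(jp0, co),
               lmm_marginal_loglik(jp0$longitudinal, co) +
                 weibull_ph_loglik(jp0$survival, co),
               tolerance = 1e-4)
  # and at the two-stage estimates on a cohort large enough to fit both
  co <- sim_cohort(n = 40, seed = 123)
  lmmf <- fit_lmm(co)
  wph <- fit_weibull_ph(co)
  jpf <- joint_params(lmmf$params, wph$params, alpha = 0, alpha_s = 0)
  expect_equal(marginal_loglik(jpf, co), lmmf$loglik + wph$loglik,
               tolerance = 1e-4)
})

test_that("estimates are invariant to subject relabeling and row order", {
  co <- sim_cohort(n = 20, seed = 55)
  jp <- default_generative_params()
  ll1 <- marginal_loglik(jp, co)
  # reverse subject labels and shuffle both tables
  relab <- setNames(sprintf("Q%02d", seq_len(20)), co$subjects$subject_id)
  s2 <- co$subjects; s2$subject_id <- unname(relab[s2$subject_id])
  o2 <- co$observations[, c("subject_id", "time_years", "psa_ng_ml")]
  o2$subject_id <- unname(relab[o2$subject_id])
  set.seed(1)
  s2 <- s2[sample(nrow(s2)), ]
  o2 <- o2[sample(nrow(o2)), ]
  co2 <- psa_cohort(s2, o2, co$transform)
  expect_equal(marginal_loglik(jp, co2), ll1, tolerance = 1e-10)
})
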