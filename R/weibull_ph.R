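# Weibull proportional-hazards fit on baseline covariates only.
# Used to initialize the survival side of the EM algorithm, and as one leg
# of the factorization identity (null-association joint likelihood =
# LMM + Weibull PH likelihoods).

#' Weibull PH log-likelihood
#'
#' \eqn{\sum_i \delta_i\{\log h_0(T_i) + \gamma^\top w_i\} -
#' H_0(T_i) e^{\gamma^\top w_i}} with a Weibull baseline.
#'
#' @param params A [survival_params()] with a Weibull baseline.
#' @param cohort A [psa_cohort()].
#' @return Scalar log-likelihood.
#' @export
weibull_ph_loglik <- function(params, cohort) {
  stopifnot(inherits(params, "surv_params"),
            inherits(params$baseline, "weibull_hazard"))
  s <- cohort$subjects
  W <- survival_design(s)
  eta <- drop(W %*% params$gamma)
  Tt <- s$event_time_years
  sum(s$event * (bh_log_hazard(params$baseline, Tt) + eta) -
        cumulative_hazard(params$baseline, Tt) * exp(eta))
}

#' Fit a Weibull proportional-hazards model on baseline covariates
#'
#' Maximum likelihood over (log shape, log scale, gamma) by BFGS.  No
#' longitudinal term is included; this is the two-stage initializer for the
#' survival side of [em_fit()].
#'
#' @param cohort A [psa_cohort()] with at least one event.
#' @return List with \code{params} (a [survival_params()]) and
#'   \code{loglik}.
#' @export
fit_weibull_ph <- function(cohort) {
  s <- cohort$subjects
  if (sum(s$event) < 1) stop("fit_weibull_ph: no events in cohort")
  W <- survival_design(s)
  Tt <- s$event_time_years
  delta <- s$event
  # center age so the scale parameter stays well-conditioned during search
  age_mean <- mean(W[, "age_years"])
  Wc <- W; Wc[, "age_years"] <- W[, "age_years"] - age_mean
  nll <- function(par) {
    k <- exp(par[1]); lam <- exp(par[2]); gam <- par[-(1:2)]
    eta <- drop(Wc %*% gam)
    lh0 <- log(k) - log(lam) + (k - 1) * (log(Tt) - log(lam))
    -sum(delta * (lh0 + eta) - (Tt / lam)^k * exp(eta))
  }
  init <- c(0, log(stats::median(Tt)) , rep(0, ncol(W)))
  opt <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  k <- exp(opt$par[1]); lam_c <- exp(opt$par[2]); gam <- opt$par[-(1:2)]
  # undo the age centering: absorb exp(gamma_age * mean age) into the scale
  lam <- lam_c * exp(gam[ncol(W)] * age_mean / k)
  params <- survival_params(gam, weibull_hazard(shape = k, scale = lam))
  list(params = params, loglik = -opt$value, convergence = opt$convergence)
}
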