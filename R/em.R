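# EM estimation of the joint model.
#
# E-step: the Gauss-Hermite grid doubles as a discrete posterior for b_i
# (reweighting the prior-standardized nodes by the conditional likelihood).
# M-step: closed-form updates for D and sigma^2 from the posterior moments;
# a quasi-Newton (BFGS with analytic gradient) block update for
# (beta, gamma, alpha, alpha_s, baseline parameters) of the expected
# complete-data log-likelihood.  A step-halving safeguard toward the
# previous iterate keeps the observed-data log-likelihood nondecreasing.

# expected complete-data loglik (survival + longitudinal parts that depend
# on phi) and its analytic gradient, at fixed posterior weights P
em_Q <- function(phi, prep, P, caches, s2, bh_template) {
  p <- ncol(prep$st$X); q <- ncol(prep$W)
  if (any(!is.finite(phi)))
    return(list(value = -1e10, grad = rep(0, length(phi))))
  beta <- phi[seq_len(p)]
  gam <- phi[p + seq_len(q)]
  a <- phi[p + q + 1]; as_ <- phi[p + q + 2]
  psi <- phi[-seq_len(p + q + 2)]
  bh <- bh_with_unconstrained(bh_template, unname(psi))
  st <- prep$st
  Pex <- P[st$subj, , drop = FALSE]
  r0 <- st$y - drop(st$X %*% beta)
  Rm <- r0 - caches$ZBt
  val_long <- -sum(Pex * Rm^2) / (2 * s2)
  Eb <- caches$Eb                                          # n x d
  grad_beta <- crossprod(st$X, r0 - rowSums(st$Z * Eb[st$subj, , drop = FALSE])) / s2

  Weta <- drop(prep$W %*% gam)
  lh0_T <- bh_log_hazard(bh, prep$Tt)
  EmT  <- drop(prep$X_T %*% beta)  + rowSums(P * caches$ZB_T)
  EdmT <- drop(prep$dX_T %*% beta) + rowSums(P * caches$dZB_T)
  val_ev <- sum(prep$delta * (lh0_T + Weta + a * EmT + as_ * EdmT))
  grad_gamma <- crossprod(prep$W, prep$delta)
  grad_a  <- sum(prep$delta * EmT)
  grad_as <- sum(prep$delta * EdmT)
  grad_beta <- grad_beta + crossprod(prep$X_T, prep$delta * a) +
    crossprod(prep$dX_T, prep$delta * as_)
  lg0_T <- bh_loggrad(bh, prep$Tt)
  grad_psi <- colSums(prep$delta * lg0_T)

  mfix_s  <- drop(prep$X_s %*% beta)
  dmfix_s <- drop(prep$dX_s %*% beta)
  logh_s <- bh_log_hazard(bh, prep$s_vec) + Weta[prep$subj_s] +
    a * (mfix_s + caches$ZB_s) + as_ * (dmfix_s + caches$dZB_s)
  A <- (prep$v_vec * exp(logh_s)) * P[prep$subj_s, , drop = FALSE]
  G <- rowSums(A)
  val_int <- -sum(G)
  Gsub <- rowsum(G, prep$subj_s)
  grad_gamma <- grad_gamma - crossprod(prep$W, Gsub)
  grad_a  <- grad_a  - sum(G * mfix_s)  - sum(A * caches$ZB_s)
  grad_as <- grad_as - sum(G * dmfix_s) - sum(A * caches$dZB_s)
  grad_beta <- grad_beta - a * crossprod(prep$X_s, G) -
    as_ * crossprod(prep$dX_s, G)
  grad_psi <- grad_psi - colSums(bh_loggrad(bh, prep$s_vec) * G)

  val <- val_long + val_ev + val_int
  grad <- c(drop(grad_beta), drop(grad_gamma), grad_a, grad_as, grad_psi)
  if (!is.finite(val) || any(!is.finite(grad)))
    return(list(value = -1e10, grad = rep(0, length(phi))))
  list(value = val, grad = grad)
}

em_estep <- function(prep, jp) {
  grid <- adaptive_grid(prep, jp$longitudinal)
  cc <- joint_ll_matrix(prep, jp, grid)
  M <- cc$ll + grid$lw
  per <- row_logsumexp(M)
  if (any(!is.finite(per)))
    stop("em_fit: non-finite likelihood contribution for subject index ",
         paste(which(!is.finite(per)), collapse = ", "))
  P <- exp(M - per)
  Eb <- vapply(grid$Bs, function(Bk) rowSums(P * Bk),
               numeric(prep$n))                       # n x d
  list(loglik = sum(per), P = P,
       caches = list(Bs = grid$Bs, Eb = Eb,
                     ZBt = cc$ZBt, ZB_T = cc$ZB_T, dZB_T = cc$dZB_T,
                     ZB_s = cc$ZB_s, dZB_s = cc$dZB_s))
}

# convex combination of two parameter sets (step-halving path)
blend_params <- function(jp_new, jp_old, w) {
  lo_n <- jp_new$longitudinal; lo_o <- jp_old$longitudinal
  sv_n <- jp_new$survival; sv_o <- jp_old$survival
  psi <- w * bh_unconstrained(sv_n$baseline) +
    (1 - w) * bh_unconstrained(sv_o$baseline)
  joint_params(
    longitudinal_params(w * lo_n$beta + (1 - w) * lo_o$beta,
                        w * lo_n$D + (1 - w) * lo_o$D,
                        w * lo_n$sigma2 + (1 - w) * lo_o$sigma2),
    survival_params(w * sv_n$gamma + (1 - w) * sv_o$gamma,
                    bh_with_unconstrained(sv_n$baseline, unname(psi))),
    alpha = w * jp_new$alpha + (1 - w) * jp_old$alpha,
    alpha_s = w * jp_new$alpha_s + (1 - w) * jp_old$alpha_s)
}

default_baseline_init <- function(family, cohort, wb) {
  ev <- cohort$subjects$event_time_years[cohort$subjects$event == 1]
  if (length(ev) < 2) ev <- cohort$subjects$event_time_years
  switch(family,
    weibull = wb,
    piecewise_constant = {
      br <- c(0, unname(stats::quantile(ev, c(0.2, 0.4, 0.6, 0.8))))
      br <- br[!duplicated(br)]
      mid <- c(br[-1] - diff(br) / 2, max(ev))
      piecewise_hazard(br, pmax(exp(bh_log_hazard(wb, mid)), 1e-4))
    },
    bspline = {
      kq <- unname(stats::quantile(ev, seq(1, 5) / 6))
      hi <- max(cohort$subjects$event_time_years) * 1.05
      kq <- kq[kq > 0 & kq < hi]
      b0 <- bspline_hazard(kq, rep(0, length(kq) + 4), c(0, hi))
      # least-squares projection of the Weibull log-hazard onto the basis
      tg <- seq(hi * 0.02, hi * 0.98, length.out = 60)
      Bas <- bspline_basis(b0, tg)
      cf <- stats::coef(stats::lm.fit(Bas, bh_log_hazard(wb, tg)))
      cf[is.na(cf)] <- 0
      bspline_hazard(kq, unname(cf), c(0, hi))
    },
    stop("unknown baseline family: ", family))
}

#' Fit the joint model by EM with Gauss-Hermite quadrature
#'
#' Two-stage initialization (standalone LMM fit and Weibull PH fit, with
#' both associations at zero) unless \code{init} is supplied.  Each EM
#' iteration reweights the Gauss-Hermite grid to obtain posterior moments
#' of the random effects (E-step), then updates D and sigma^2 in closed
#' form and the remaining parameters by a quasi-Newton block with analytic
#' gradients (M-step).  Step-halving toward the previous iterate guarantees
#' a nondecreasing observed-data log-likelihood.  Convergence when the
#' relative log-likelihood change is below \code{tol_loglik} or the sup
#' change of the (unconstrained) parameter vector is below
#' \code{tol_params}.
#'
#' @param cohort A [psa_cohort()] with at least one event.
#' @param spec,re_spec Design specifications.
#' @param rule A [quadrature_rule()].
#' @param baseline_family One of \code{"weibull"},
#'   \code{"piecewise_constant"}, \code{"bspline"}.
#' @param init Optional [joint_params()] starting value.
#' @param max_iter Iteration cap (default 300); reaching it returns a
#'   FitResult flagged non-converged rather than an error.
#' @param tol_loglik,tol_params Convergence tolerances (defaults 1e-8, 1e-6).
#' @param mstep_iter BFGS iterations per M-step block update (default 20).
#' @param compute_se Also compute standard errors via [standard_errors()]?
#' @return Object of class \code{joint_fit}: \code{params}, \code{se} (or
#'   NULL), \code{loglik}, \code{aic}, \code{n_params}, \code{n_iter},
#'   \code{converged}, \code{trace} (per-iteration log-likelihood).
#' @export
em_fit <- function(cohort, spec = fixed_effects_spec(),
                   re_spec = random_effects_spec(),
                   rule = quadrature_rule(),
                   baseline_family = c("weibull", "piecewise_constant",
                                       "bspline"),
                   init = NULL, max_iter = 300,
                   tol_loglik = 1e-8, tol_params = 1e-6,
                   mstep_iter = 20, compute_se = FALSE) {
  baseline_family <- match.arg(baseline_family)
  if (sum(cohort$subjects$event) < 1) stop("em_fit: cohort has no events")
  if (is.null(init)) {
    lmmf <- fit_lmm(cohort, spec, re_spec)
    wph <- fit_weibull_ph(cohort)
    bh0 <- default_baseline_init(baseline_family, cohort,
                                 wph$params$baseline)
    init <- joint_params(lmmf$params,
                         survival_params(wph$params$gamma, bh0),
                         alpha = 0, alpha_s = 0)
  }
  prep <- prepare_joint(cohort, spec, re_spec, rule,
                        time_power = baseline_time_power(
                          init$survival$baseline))
  jp <- init
  es <- em_estep(prep, jp)
  trace <- es$loglik
  converged <- FALSE
  iter <- 0
  p <- ncol(prep$st$X); q <- ncol(prep$W)
  while (iter < max_iter) {
    iter <- iter + 1
    # closed-form variance-component updates from posterior moments
    d <- prep$d
    D_new <- matrix(0, d, d)
    for (k in seq_len(d)) for (m in k:d)
      D_new[k, m] <- D_new[m, k] <-
        sum(es$P * es$caches$Bs[[k]] * es$caches$Bs[[m]]) / prep$n
    if (inherits(try(chol(D_new), silent = TRUE), "try-error"))
      stop("em_fit: D lost positive-definiteness at iteration ", iter)
    phi0 <- c(jp$longitudinal$beta, jp$survival$gamma, jp$alpha, jp$alpha_s,
              bh_unconstrained(jp$survival$baseline))
    s2_cur <- jp$longitudinal$sigma2
    qc <- new.env(parent = emptyenv())
    qeval <- function(ph) {
      if (is.null(qc$ph) || !identical(ph, qc$ph)) {
        qc$ph <- ph
        qc$res <- em_Q(ph, prep, es$P, es$caches, s2_cur,
                       jp$survival$baseline)
      }
      qc$res
    }
    opt <- stats::optim(phi0,
                        fn = function(ph) -qeval(ph)$value,
                        gr = function(ph) -qeval(ph)$grad,
                        method = "BFGS",
                        control = list(maxit = mstep_iter))
    phi <- opt$par
    beta_new <- stats::setNames(phi[seq_len(p)], names(jp$longitudinal$beta))
    gam_new <- phi[p + seq_len(q)]
    a_new <- unname(phi[p + q + 1]); as_new <- unname(phi[p + q + 2])
    bh_new <- bh_with_unconstrained(jp$survival$baseline,
                                    unname(phi[-seq_len(p + q + 2)]))
    # sigma^2 closed form at the new beta
    r0 <- prep$st$y - drop(prep$st$X %*% beta_new)
    s2_new <- sum(es$P[prep$st$subj, , drop = FALSE] *
                    (r0 - es$caches$ZBt)^2) / prep$st$N
    jp_new <- joint_params(
      longitudinal_params(beta_new, D_new, s2_new),
      survival_params(gam_new, bh_new),
      alpha = a_new, alpha_s = as_new)
    # safeguard: accept only if the observed-data loglik did not decrease
    es_new <- em_estep(prep, jp_new)
    halvings <- 0
    while (es_new$loglik < utils::tail(trace, 1) - 1e-10 && halvings < 12) {
      halvings <- halvings + 1
      jp_new <- blend_params(jp_new, jp, 0.5)
      es_new <- em_estep(prep, jp_new)
    }
    if (es_new$loglik < utils::tail(trace, 1) - 1e-10) {
      converged <- TRUE            # no ascent direction left
      break
    }
    dtheta <- max(abs(joint_to_theta(jp_new) - joint_to_theta(jp)))
    ll_old <- utils::tail(trace, 1)
    jp <- jp_new; es <- es_new
    trace <- c(trace, es$loglik)
    rel <- abs(es$loglik - ll_old) / (abs(ll_old) + 0.1)
    if (rel < tol_loglik || dtheta < tol_params) {
      converged <- TRUE
      break
    }
  }
  npar <- length(joint_to_theta(jp))
  fit <- structure(list(params = jp, se = NULL, loglik = utils::tail(trace, 1),
                        aic = 2 * npar - 2 * utils::tail(trace, 1),
                        n_params = npar, n_iter = iter,
                        converged = converged, trace = trace,
                        spec = spec, re_spec = re_spec, rule = rule,
                        baseline_family = baseline_family),
                   class = "joint_fit")
  if (compute_se) fit <- standard_errors(fit, cohort, rule)
  fit
}

#' @export
print.joint_fit <- function(x, ...) {
  cat("Joint longitudinal-survival model fit (", x$baseline_family,
      " baseline)\n", sep = "")
  cat(sprintf("  log-likelihood %.3f, AIC %.3f, %d parameters\n",
              x$loglik, x$aic, x$n_params))
  cat(sprintf("  %d EM iterations, converged: %s\n", x$n_iter, x$converged))
  cat(sprintf("  alpha (current value) %.4f, alpha_s (slope) %.4f\n",
              x$params$alpha, x$params$alpha_s))
  invisible(x)
}

#' Standard errors from the observed-information matrix
#'
#' Numerical Hessian of the marginal log-likelihood at the estimate
#' (central differences, relative step 1e-5) over the full unconstrained
#' parameter vector; standard errors are the square roots of the diagonal
#' of the inverse negative Hessian.
#'
#' @param fit A [em_fit()] result.
#' @param cohort The cohort the model was fit to.
#' @param rule A [quadrature_rule()] (defaults to the fit's rule).
#' @return The fit with \code{se} (named vector) filled in.
#' @export
standard_errors <- function(fit, cohort, rule = fit$rule) {
  prep <- prepare_joint(cohort, fit$spec, fit$re_spec, rule,
                        time_power = baseline_time_power(
                          fit$params$survival$baseline))
  template <- fit$params
  f <- function(th) {
    jp <- theta_to_joint(th, template)
    grid <- adaptive_grid(prep, jp$longitudinal)
    sum(marginal_from_ll(joint_ll_matrix(prep, jp, grid)$ll, grid$lw))
  }
  th0 <- joint_to_theta(template)
  H <- central_hessian(f, th0, rel_step = 1e-5)
  Hn <- -H
  ev <- eigen((Hn + t(Hn)) / 2, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    flat <- names(th0)[which.max(abs(ev$vectors[, which.min(ev$values)]))]
    stop("standard_errors: information matrix is singular; flattest ",
         "direction involves parameter '", flat, "'")
  }
  cov <- ev$vectors %*% diag(1 / ev$values, length(th0)) %*% t(ev$vectors)
  fit$se <- stats::setNames(sqrt(diag(cov)), names(th0))
  fit$vcov <- structure(cov, dimnames = list(names(th0), names(th0)))
  fit
}

central_hessian <- function(f, x, rel_step = 1e-5) {
  p <- length(x)
  h <- rel_step * pmax(abs(x), 1)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < p) for (j in (i + 1):p) {
      ej <- numeric(p); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}
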