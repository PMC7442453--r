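# Standalone linear mixed model for the transformed-PSA trajectory:
# y_i ~ N(X_i beta, Z_i D Z_i' + sigma^2 I).  Maximum (marginal) likelihood
# with beta profiled out by GLS and (D, sigma^2) on a log-Cholesky scale.
# Used to initialize the EM algorithm and in the factorization identity.

# stack designs for the whole cohort; obs ordered by subject
stack_longitudinal <- function(cohort, spec, re_spec) {
  s <- cohort$subjects
  o <- cohort$observations[order(match(cohort$observations$subject_id,
                                       s$subject_id)), ]
  idx <- match(o$subject_id, s$subject_id)
  X <- NULL; Z <- NULL
  parts <- lapply(seq_len(nrow(s)), function(i) {
    ti <- o$time_years[idx == i]
    build_design(s[i, ], ti, spec, re_spec)
  })
  X <- do.call(rbind, lapply(parts, `[[`, "X"))
  Z <- do.call(rbind, lapply(parts, `[[`, "Z"))
  list(X = X, Z = Z, y = o$psa_star, subj = idx, obs = o,
       n = nrow(s), N = nrow(o))
}

# log-Cholesky <-> covariance helpers (lower triangular, log on diagonal)
chol_to_theta <- function(D) {
  L <- t(chol(D))
  d <- nrow(D)
  th <- c()
  for (j in seq_len(d)) for (i in j:d)
    th <- c(th, if (i == j) log(L[i, j]) else L[i, j])
  th
}
theta_to_chol <- function(th, d) {
  L <- matrix(0, d, d)
  k <- 1
  for (j in seq_len(d)) for (i in j:d) {
    L[i, j] <- if (i == j) exp(th[k]) else th[k]
    k <- k + 1
  }
  L
}

#' Marginal log-likelihood of the linear mixed model
#'
#' Direct matrix-form Gaussian marginal likelihood with per-subject
#' covariance \eqn{V_i = Z_i D Z_i^\top + \sigma^2 I}.
#'
#' @param params A [longitudinal_params()].
#' @param cohort A [psa_cohort()].
#' @param spec,re_spec Design specifications.
#' @return Scalar log-likelihood.
#' @export
lmm_marginal_loglik <- function(params, cohort,
                                spec = fixed_effects_spec(),
                                re_spec = random_effects_spec()) {
  st <- stack_longitudinal(cohort, spec, re_spec)
  r <- st$y - drop(st$X %*% params$beta)
  ll <- 0
  for (i in seq_len(st$n)) {
    rows <- st$subj == i
    Zi <- st$Z[rows, , drop = FALSE]
    Vi <- Zi %*% params$D %*% t(Zi) + diag(params$sigma2, sum(rows))
    ri <- r[rows]
    ch <- chol(Vi)
    ll <- ll - 0.5 * (sum(rows) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        sum(backsolve(ch, ri, transpose = TRUE)^2))
  }
  ll
}

#' Fit the linear mixed trajectory model by maximum likelihood
#'
#' Profiles the fixed effects by generalized least squares and maximizes the
#' marginal likelihood over the variance components with BFGS on a
#' log-Cholesky parameterization of D (positive-definiteness by
#' construction).  Convergence: relative log-likelihood change below 1e-8
#' within the iteration cap.
#'
#' @param cohort A [psa_cohort()] with at least 2 subjects.
#' @param spec,re_spec Design specifications.
#' @param max_iter Iteration cap for the optimizer (default 500).
#' @return List with \code{params} (a [longitudinal_params()]),
#'   \code{loglik}, and \code{convergence} (0 = converged).
#' @export
fit_lmm <- function(cohort, spec = fixed_effects_spec(),
                    re_spec = random_effects_spec(), max_iter = 500) {
  st <- stack_longitudinal(cohort, spec, re_spec)
  if (st$n < 2) stop("fit_lmm: need at least 2 subjects")
  d <- ncol(st$Z); p <- ncol(st$X)
  rows_i <- split(seq_len(st$N), st$subj)

  profile <- function(th) {
    if (any(!is.finite(th)) || any(abs(th) > 20))
      return(list(ll = -1e10, beta = NULL, D = NULL, sigma2 = NULL))
    L <- theta_to_chol(th[seq_len(d * (d + 1) / 2)], d)
    D <- L %*% t(L)
    s2 <- exp(th[length(th)])
    XtVX <- matrix(0, p, p); XtVy <- numeric(p)
    chs <- vector("list", st$n)
    for (i in seq_len(st$n)) {
      rows <- rows_i[[i]]
      Zi <- st$Z[rows, , drop = FALSE]
      Vi <- Zi %*% D %*% t(Zi) + diag(s2, length(rows))
      ch <- chol(Vi)
      Xi <- st$X[rows, , drop = FALSE]
      Wx <- backsolve(ch, Xi, transpose = TRUE)
      Wy <- backsolve(ch, st$y[rows], transpose = TRUE)
      XtVX <- XtVX + crossprod(Wx)
      XtVy <- XtVy + crossprod(Wx, Wy)
      chs[[i]] <- ch
    }
    beta <- solve(XtVX, XtVy)
    ll <- 0
    for (i in seq_len(st$n)) {
      rows <- rows_i[[i]]
      ri <- st$y[rows] - drop(st$X[rows, , drop = FALSE] %*% beta)
      ch <- chs[[i]]
      ll <- ll - 0.5 * (length(rows) * log(2 * pi) +
                          2 * sum(log(diag(ch))) +
                          sum(backsolve(ch, ri, transpose = TRUE)^2))
    }
    list(ll = ll, beta = drop(beta), D = D, sigma2 = s2)
  }

  # moment-based start: OLS residual variance split between RE and noise
  beta0 <- stats::coef(stats::lm.fit(st$X, st$y))
  beta0[!is.finite(beta0)] <- 0
  v0 <- stats::var(st$y - drop(st$X %*% beta0))
  if (!is.finite(v0) || v0 <= 0) v0 <- max(stats::var(st$y), 1e-2)
  D0 <- diag(rep(max(v0 / 2, 1e-3), d), d)
  th0 <- c(chol_to_theta(D0), log(max(v0 / 2, 1e-3)))
  nll <- function(th) {
    ll <- tryCatch(profile(th)$ll, error = function(e) -1e10)
    if (!is.finite(ll)) ll <- -1e10
    -ll
  }
  opt <- stats::optim(th0, nll, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-10))
  if (opt$convergence != 0 && opt$convergence != 1)
    stop("fit_lmm: optimizer failed (code ", opt$convergence, "): ",
         opt$message)
  best <- profile(opt$par)
  params <- longitudinal_params(stats::setNames(best$beta, spec$terms),
                                best$D, best$sigma2)
  list(params = params, loglik = best$ll, convergence = opt$convergence)
}
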