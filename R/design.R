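# Fixed- and random-effects design for the transformed-PSA trajectory.
#
# The default fixed-effect structure mirrors the longitudinal sub-model
# reported for this cohort: intercept, hormone therapy, two dose-group
# contrasts (reference <=50 Gy), linear time, and time-by-hormone /
# time-by-dose interactions.  Quadratic time is opt-in.

#' Fixed-effects specification for the trajectory sub-model
#'
#' @param include_quadratic_time Add a \code{time^2} term? Default \code{FALSE}.
#' @return Object of class \code{fe_spec} with an ordered \code{terms} vector.
#' @export
fixed_effects_spec <- function(include_quadratic_time = FALSE) {
  terms <- c("intercept", "hormone_therapy", "dose_51_69", "dose_ge70",
             "time",
             if (include_quadratic_time) "time2",
             "time_hormone", "time_dose_51_69", "time_dose_ge70")
  structure(list(terms = terms,
                 include_quadratic_time = include_quadratic_time),
            class = "fe_spec")
}

#' Random-effects specification for the trajectory sub-model
#'
#' Random intercept plus random time slope by default; an intercept-only
#' structure is supported for degenerate/reference fits.
#'
#' @param terms Character subset of \code{c("intercept", "time")}.
#' @return Object of class \code{re_spec}.
#' @export
random_effects_spec <- function(terms = c("intercept", "time")) {
  terms <- match.arg(terms, c("intercept", "time"), several.ok = TRUE)
  structure(list(terms = terms, dim = length(terms)), class = "re_spec")
}

subject_dummies <- function(subject) {
  list(h  = as.numeric(subject$hormone_therapy),
       d2 = as.numeric(subject$dose_group == "51-69"),
       d3 = as.numeric(subject$dose_group == "ge70"))
}

#' Build fixed and random design matrices for one subject
#'
#' @param subject One-row data frame with the baseline covariates of a
#'   [psa_cohort()] subjects table.
#' @param times Numeric vector of visit times (years, >= 0).
#' @param spec A [fixed_effects_spec()].
#' @param re_spec A [random_effects_spec()].
#' @param derivative If \code{TRUE}, return the time-derivatives of the
#'   design rows instead (used for the trajectory slope).
#' @return List with matrices \code{X} (length(times) x p, columns ordered
#'   per \code{spec$terms}) and \code{Z} (length(times) x RE dimension).
#' @export
build_design <- function(subject, times, spec = fixed_effects_spec(),
                         re_spec = random_effects_spec(),
                         derivative = FALSE) {
  stopifnot(inherits(spec, "fe_spec"), inherits(re_spec, "re_spec"))
  if (any(times < 0)) stop("build_design: times must be >= 0")
  if (!subject$dose_group %in% DOSE_LEVELS)
    stop("build_design: unknown dose_group level: ", subject$dose_group)
  d <- subject_dummies(subject)
  n <- length(times)
  one <- rep(1, n); zero <- rep(0, n)
  cols <- if (!derivative) list(
    intercept       = one,
    hormone_therapy = rep(d$h, n),
    dose_51_69      = rep(d$d2, n),
    dose_ge70       = rep(d$d3, n),
    time            = times,
    time2           = times^2,
    time_hormone    = times * d$h,
    time_dose_51_69 = times * d$d2,
    time_dose_ge70  = times * d$d3
  ) else list(
    intercept       = zero,
    hormone_therapy = zero,
    dose_51_69      = zero,
    dose_ge70       = zero,
    time            = one,
    time2           = 2 * times,
    time_hormone    = rep(d$h, n),
    time_dose_51_69 = rep(d$d2, n),
    time_dose_ge70  = rep(d$d3, n)
  )
  X <- do.call(cbind, cols[spec$terms])
  zcols <- list(intercept = if (derivative) zero else one,
                time      = if (derivative) one else times)
  Z <- do.call(cbind, zcols[re_spec$terms])
  colnames(Z) <- re_spec$terms
  list(X = X, Z = Z)
}

#' Parameters of the longitudinal sub-model
#'
#' @param beta Fixed-effect coefficients, ordered per [fixed_effects_spec()].
#' @param D Random-effects covariance matrix (symmetric positive-definite).
#' @param sigma2 Residual variance (> 0).
#' @return Object of class \code{long_params}.
#' @export
longitudinal_params <- function(beta, D, sigma2) {
  D <- as.matrix(D)
  stopifnot(sigma2 > 0, isSymmetric(unname(D)))
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("longitudinal_params: D is not positive-definite")
  structure(list(beta = beta, D = D, sigma2 = sigma2), class = "long_params")
}

#' Error-free trajectory value m_i(t)
#'
#' Evaluates \eqn{m_i(t) = x_i(t)^\top \beta + z_i(t)^\top b_i} on the
#' transformed-PSA scale (measurement noise excluded).
#'
#' @param params A [longitudinal_params()] (or any list with \code{beta}).
#' @param b_i Random-effect vector for the subject.
#' @param subject One-row baseline data frame.
#' @param t Time(s) in years.
#' @param spec,re_spec Design specifications.
#' @return Numeric vector, transformed-PSA units.
#' @export
trajectory_value <- function(params, b_i, subject, t,
                             spec = fixed_effects_spec(),
                             re_spec = random_effects_spec()) {
  dm <- build_design(subject, t, spec, re_spec)
  if (length(params$beta) != ncol(dm$X))
    stop("trajectory_value: beta length ", length(params$beta),
         " does not match design with ", ncol(dm$X), " columns")
  if (length(b_i) != ncol(dm$Z))
    stop("trajectory_value: b_i length does not match random-effects design")
  drop(dm$X %*% params$beta + dm$Z %*% b_i)
}

#' Trajectory slope m_i'(t)
#'
#' Analytic time-derivative of [trajectory_value()]; constant in \code{t}
#' for the linear-time specification.
#'
#' @inheritParams trajectory_value
#' @return Numeric vector, transformed-PSA units per year.
#' @export
trajectory_slope <- function(params, b_i, subject, t,
                             spec = fixed_effects_spec(),
                             re_spec = random_effects_spec()) {
  dm <- build_design(subject, t, spec, re_spec, derivative = TRUE)
  if (length(params$beta) != ncol(dm$X))
    stop("trajectory_slope: beta length does not match design")
  if (length(b_i) != ncol(dm$Z))
    stop("trajectory_slope: b_i length does not match random-effects design")
  drop(dm$X %*% params$beta + dm$Z %*% b_i)
}
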