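# Baseline-hazard families for the proportional-hazards sub-model.
#
# Three families share one contract: h0(t) > 0 for t > 0, H0 continuous and
# nondecreasing with H0(0) = 0.  Weibull and piecewise-constant cumulative
# hazards are closed form; the B-spline family integrates exp(spline)
# adaptively.  Inside the joint likelihood all families are integrated with
# a fixed Gauss-Legendre rule instead (see quadrature_rule()).

#' Weibull baseline hazard
#'
#' Shape/scale parameterization with hazard
#' \eqn{h_0(t) = (k/\lambda)(t/\lambda)^{k-1}} and cumulative hazard
#' \eqn{(t/\lambda)^k}.
#'
#' @param shape Shape k > 0.
#' @param scale Scale lambda > 0 (years).
#' @return Object of classes \code{weibull_hazard}, \code{baseline_hazard}.
#' @export
weibull_hazard <- function(shape = 1, scale = 1) {
  stopifnot(shape > 0, scale > 0)
  structure(list(family = "weibull", shape = shape, scale = scale),
            class = c("weibull_hazard", "baseline_hazard"))
}

#' Piecewise-constant baseline hazard
#'
#' Right-open intervals: height \code{heights[j]} applies on
#' \code{[breaks[j], breaks[j+1])}, the last height on
#' \code{[breaks[m], Inf)}.  \code{breaks[1]} must be 0.
#'
#' @param breaks Increasing knot grid starting at 0.
#' @param heights Positive hazard heights, one per interval.
#' @return Object of classes \code{piecewise_hazard}, \code{baseline_hazard}.
#' @export
piecewise_hazard <- function(breaks, heights) {
  stopifnot(length(heights) == length(breaks),
            breaks[1] == 0, !is.unsorted(breaks, strictly = TRUE),
            all(heights > 0))
  structure(list(family = "piecewise_constant", breaks = breaks,
                 heights = heights),
            class = c("piecewise_hazard", "baseline_hazard"))
}

#' Cubic B-spline baseline hazard on the log scale
#'
#' \eqn{\log h_0(t)} is a cubic B-spline on \code{[boundary[1], boundary[2]]}
#' with the given internal knots; the log-hazard is extended as a constant
#' beyond the boundary knots.
#'
#' @param knots Internal knots (years), strictly inside \code{boundary}.
#' @param coef Spline coefficients of the log-hazard
#'   (length \code{length(knots) + 4}).
#' @param boundary Boundary knots, default \code{c(0, max(knots) * 1.5)}.
#' @return Object of classes \code{bspline_hazard}, \code{baseline_hazard}.
#' @export
bspline_hazard <- function(knots, coef, boundary = NULL) {
  if (is.null(boundary)) boundary <- c(0, max(knots) * 1.5)
  stopifnot(all(knots > boundary[1]), all(knots < boundary[2]),
            length(coef) == length(knots) + 4L)
  structure(list(family = "bspline", knots = knots, coef = coef,
                 boundary = boundary),
            class = c("bspline_hazard", "baseline_hazard"))
}

bspline_basis <- function(b, t) {
  tc <- pmin(pmax(t, b$boundary[1]), b$boundary[2])
  aug <- c(rep(b$boundary[1], 4), b$knots, rep(b$boundary[2], 4))
  splines::splineDesign(aug, tc, ord = 4)
}

# --- internal generics used by the likelihood engine -------------------------

bh_log_hazard <- function(b, t) UseMethod("bh_log_hazard")
#' @export
bh_log_hazard.weibull_hazard <- function(b, t)
  log(b$shape) - log(b$scale) + (b$shape - 1) * (log(t) - log(b$scale))
#' @export
bh_log_hazard.piecewise_hazard <- function(b, t)
  log(b$heights)[findInterval(t, b$breaks)]
#' @export
bh_log_hazard.bspline_hazard <- function(b, t)
  drop(bspline_basis(b, t) %*% b$coef)

# unconstrained parameter vector for optimization
bh_unconstrained <- function(b) UseMethod("bh_unconstrained")
#' @export
bh_unconstrained.weibull_hazard <- function(b)
  c(log_shape = log(b$shape), log_scale = log(b$scale))
#' @export
bh_unconstrained.piecewise_hazard <- function(b)
  stats::setNames(log(b$heights), paste0("log_h", seq_along(b$heights)))
#' @export
bh_unconstrained.bspline_hazard <- function(b)
  stats::setNames(b$coef, paste0("spline_c", seq_along(b$coef)))

bh_with_unconstrained <- function(b, psi) UseMethod("bh_with_unconstrained")
#' @export
bh_with_unconstrained.weibull_hazard <- function(b, psi) {
  psi <- pmin(pmax(psi, -30), 30)
  weibull_hazard(shape = exp(psi[1]), scale = exp(psi[2]))
}
#' @export
bh_with_unconstrained.piecewise_hazard <- function(b, psi)
  piecewise_hazard(b$breaks, exp(psi))
#' @export
bh_with_unconstrained.bspline_hazard <- function(b, psi)
  bspline_hazard(b$knots, as.numeric(psi), b$boundary)

# d log h0(t) / d psi, as length(t) x npar matrix
bh_loggrad <- function(b, t) UseMethod("bh_loggrad")
#' @export
bh_loggrad.weibull_hazard <- function(b, t)
  cbind(1 + b$shape * (log(t) - log(b$scale)), rep(-b$shape, length(t)))
#' @export
bh_loggrad.piecewise_hazard <- function(b, t) {
  idx <- findInterval(t, b$breaks)
  m <- matrix(0, length(t), length(b$heights))
  m[cbind(seq_along(t), idx)] <- 1
  m
}
#' @export
bh_loggrad.bspline_hazard <- function(b, t) bspline_basis(b, t)

# --- exported evaluation ------------------------------------------------------

#' Evaluate a baseline hazard
#'
#' @param b A baseline-hazard object ([weibull_hazard()],
#'   [piecewise_hazard()] or [bspline_hazard()]).
#' @param t Time(s) in years, > 0.
#' @return Hazard rate(s), per year.
#' @export
baseline_hazard <- function(b, t) {
  stopifnot(inherits(b, "baseline_hazard"))
  if (any(t <= 0)) stop("baseline_hazard: t must be > 0")
  exp(bh_log_hazard(b, t))
}

#' Cumulative baseline hazard H0(t)
#'
#' Closed form for the Weibull and piecewise-constant families; adaptive
#' quadrature (relative tolerance 1e-8) for the B-spline family.
#'
#' @inheritParams baseline_hazard
#' @param t Time(s) in years, >= 0.
#' @return Dimensionless cumulative hazard(s); 0 at t = 0.
#' @export
cumulative_hazard <- function(b, t) {
  stopifnot(inherits(b, "baseline_hazard"))
  if (any(t < 0)) stop("cumulative_hazard: t must be >= 0")
  if (inherits(b, "weibull_hazard")) return((t / b$scale)^b$shape)
  if (inherits(b, "piecewise_hazard")) {
    vapply(t, function(ti) {
      if (ti == 0) return(0)
      up <- c(b$breaks[-1], Inf)
      widths <- pmax(0, pmin(ti, up) - pmin(ti, b$breaks))
      sum(widths * b$heights)
    }, numeric(1))
  } else {
    vapply(t, function(ti) {
      if (ti == 0) return(0)
      stats::integrate(function(s) exp(bh_log_hazard(b, s)), 0, ti,
                       rel.tol = 1e-8, abs.tol = 0)$value
    }, numeric(1))
  }
}

#' Survival sub-model parameters
#'
#' @param gamma Named log relative-risk coefficients for the baseline
#'   covariates, in the order \code{hormone_therapy, dose_51_69, dose_ge70,
#'   stage_3_4, gleason_6, gleason_7, gleason_8_10, age_years}.
#' @param baseline A baseline-hazard object.
#' @return Object of class \code{surv_params}.
#' @export
survival_params <- function(gamma, baseline = weibull_hazard()) {
  stopifnot(inherits(baseline, "baseline_hazard"),
            length(gamma) == length(SURV_COVARIATES))
  structure(list(gamma = stats::setNames(as.numeric(gamma), SURV_COVARIATES),
                 baseline = baseline),
            class = "surv_params")
}

SURV_COVARIATES <- c("hormone_therapy", "dose_51_69", "dose_ge70",
                     "stage_3_4", "gleason_6", "gleason_7", "gleason_8_10",
                     "age_years")

# n x 8 covariate matrix in the fixed reporting order
survival_design <- function(subjects) {
  cbind(hormone_therapy = as.numeric(subjects$hormone_therapy),
        dose_51_69      = as.numeric(subjects$dose_group == "51-69"),
        dose_ge70       = as.numeric(subjects$dose_group == "ge70"),
        stage_3_4       = as.numeric(subjects$stage_group == "3-4"),
        gleason_6       = as.numeric(subjects$gleason_group == "6"),
        gleason_7       = as.numeric(subjects$gleason_group == "7"),
        gleason_8_10    = as.numeric(subjects$gleason_group == "8-10"),
        age_years       = as.numeric(subjects$age_years))
}

#' Subject-specific hazard under the joint model
#'
#' \eqn{h_i(t) = h_0(t)\exp\{\gamma^\top w_i + \alpha m_i(t) +
#' \alpha_s m_i'(t)\}} where \eqn{m_i} is the error-free transformed-PSA
#' trajectory and \eqn{m_i'} its slope.
#'
#' @param joint A [joint_params()].
#' @param b_i Random-effect vector.
#' @param subject One-row baseline data frame.
#' @param t Time(s), years, > 0.
#' @param spec,re_spec Design specifications.
#' @return Hazard rate(s), per year (strictly positive).
#' @export
subject_hazard <- function(joint, b_i, subject, t,
                           spec = fixed_effects_spec(),
                           re_spec = random_effects_spec()) {
  stopifnot(inherits(joint, "joint_params"))
  if (any(t <= 0)) stop("subject_hazard: t must be > 0")
  m  <- trajectory_value(joint$longitudinal, b_i, subject, t, spec, re_spec)
  ms <- trajectory_slope(joint$longitudinal, b_i, subject, t, spec, re_spec)
  w  <- drop(survival_design(subject))
  lp <- sum(joint$survival$gamma * w) + joint$alpha * m + joint$alpha_s * ms
  exp(bh_log_hazard(joint$survival$baseline, t) + lp)
}
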