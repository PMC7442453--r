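# Relative-risk reporting for the hazard sub-model and the associations.

#' Relative risk from a log-hazard coefficient
#'
#' @param coef Coefficient on the log-hazard scale.
#' @return \code{exp(coef)}, the hazard ratio for a one-unit increase.
#' @export
rr_from_coef <- function(coef) exp(coef)

#' Percent change in risk implied by a relative risk
#'
#' @param rr Relative risk (> 0).
#' @return \code{100 * (rr - 1)}; negative values are risk reductions.
#' @export
pct_change <- function(rr) 100 * (rr - 1)

#' Relative-risk table for a fitted joint model
#'
#' One row per hazard-scale parameter (baseline covariates, current-value
#' association alpha, slope association alpha_s): coefficient, standard
#' error, RR = exp(coef), Wald 95% CI exp(coef +/- 1.96 SE), percent change
#' 100 (RR - 1), and a two-sided Wald p-value.  Rows without a standard
#' error (fit not passed through [standard_errors()]) are emitted with NA
#' CI/p-value and flagged.
#'
#' @param fit A [em_fit()] result (ideally with standard errors).
#' @return Data frame with columns \code{parameter, coef, se, rr, ci_low,
#'   ci_high, pct_change, p_value, se_available}.
#' @export
rr_table <- function(fit) {
  stopifnot(inherits(fit, "joint_fit"))
  jp <- fit$params
  coefs <- c(jp$survival$gamma, alpha = jp$alpha, alpha_s = jp$alpha_s)
  se_names <- c(paste0("gamma.", names(jp$survival$gamma)),
                "alpha", "alpha_s")
  se <- if (is.null(fit$se)) stats::setNames(rep(NA_real_, length(coefs)),
                                             se_names)
        else fit$se[se_names]
  rr <- rr_from_coef(coefs)
  z <- coefs / se
  out <- data.frame(
    parameter = names(coefs),
    coef = unname(coefs),
    se = unname(se),
    rr = unname(rr),
    ci_low = unname(exp(coefs - 1.96 * se)),
    ci_high = unname(exp(coefs + 1.96 * se)),
    pct_change = unname(pct_change(rr)),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    se_available = !is.na(unname(se)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare baseline-hazard families by AIC
#'
#' Fits the joint model under each requested baseline family and ranks the
#' fits by AIC = 2p - 2 loglik; ties are broken toward fewer parameters.
#' A family whose fit fails is recorded with its error message rather than
#' aborting the comparison.
#'
#' @param cohort A [psa_cohort()].
#' @param spec,re_spec Design specifications.
#' @param rule A [quadrature_rule()].
#' @param families Character vector of baseline families to fit.
#' @param ... Further arguments passed to [em_fit()].
#' @return List with \code{table} (family, loglik, n_params, aic, converged,
#'   best flag, ordered by rank), \code{best} (winning family name) and
#'   \code{fits} (named list of successful fits).
#' @export
compare_baselines <- function(cohort, spec = fixed_effects_spec(),
                              re_spec = random_effects_spec(),
                              rule = quadrature_rule(),
                              families = c("weibull", "piecewise_constant",
                                           "bspline"), ...) {
  fits <- list(); errs <- list()
  for (fam in families) {
    res <- try(em_fit(cohort, spec, re_spec, rule, baseline_family = fam,
                      ...), silent = TRUE)
    if (inherits(res, "try-error")) errs[[fam]] <- as.character(res)
    else fits[[fam]] <- res
  }
  if (!length(fits))
    stop("compare_baselines: every family failed:\n",
         paste(unlist(errs), collapse = "\n"))
  tab <- data.frame(
    family = names(fits),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE)
  tab$aic <- 2 * tab$n_params - 2 * tab$loglik
  tab <- tab[order(tab$aic, tab$n_params), ]
  tab$best <- seq_len(nrow(tab)) == 1L
  rownames(tab) <- NULL
  list(table = tab, best = tab$family[1], fits = fits, failures = errs)
}
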