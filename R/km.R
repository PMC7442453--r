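#' Kaplan-Meier estimate with Greenwood confidence bands
#'
#' Product-limit estimator of the recurrence-free survival function with
#' pointwise 95% confidence intervals (Greenwood variance, log-log
#' transformed bands) and the median survival time with its CI.  The median
#' is the earliest time at which the estimated survival drops to 0.5 or
#' below; if survival never reaches 0.5 it is reported as not reached (NA).
#'
#' @param times Positive follow-up times (years).
#' @param events 0/1 event indicators (1 = recurrence/metastasis).
#' @return Object of class \code{km_fit}: list with \code{table} (data frame
#'   of time, at_risk, events, survival, ci_low, ci_high), \code{median},
#'   \code{median_ci}, and the underlying \code{survival::survfit} object.
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0L) stop("kaplan_meier: empty input")
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "log-log")
  tab <- data.frame(time = sf$time, at_risk = sf$n.risk, events = sf$n.event,
                    survival = sf$surv, ci_low = sf$lower, ci_high = sf$upper)
  qt <- stats::quantile(sf, probs = 0.5)
  med <- unname(qt$quantile)
  structure(list(table = tab, median = med,
                 median_ci = c(lower = unname(qt$lower),
                               upper = unname(qt$upper)),
                 survfit = sf),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier estimate:", max(x$table$at_risk), "subjects,",
      sum(x$table$events), "events\n")
  if (is.na(x$median)) cat("  median survival: not reached\n")
  else cat(sprintf("  median survival: %.2f years (95%% CI %.2f-%.2f)\n",
                   x$median, x$median_ci["lower"], x$median_ci["upper"]))
  invisible(x)
}

#' Write a Kaplan-Meier table to TSV
#'
#' @param km A [kaplan_meier()] fit.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_km <- function(km, path) {
  stopifnot(inherits(km, "km_fit"))
  utils::write.table(km$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
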