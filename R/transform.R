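#' PSA transformation specification
#'
#' Post-radiotherapy PSA is strongly right-skewed, so the longitudinal
#' sub-model is fit on a transformed scale.  The default is the shifted
#' natural logarithm \eqn{\log(\mathrm{PSA} + 0.1)}, the dominant convention
#' in the PSA joint-modelling literature; \code{sqrt} and \code{identity}
#' are available as alternatives.
#'
#' @param name One of \code{"log_shift"}, \code{"sqrt"}, \code{"identity"}.
#' @param shift Offset in ng/ml added before the log (only used by
#'   \code{log_shift}).  Default 0.1.
#' @param psa_range Plausibility range (ng/ml); raw values outside it are
#'   rejected on read.  Default \code{c(0, 1000)} (exclusive lower bound).
#' @return An object of class \code{transform_spec}.
#' @export
transform_spec <- function(name = c("log_shift", "sqrt", "identity"),
                           shift = 0.1, psa_range = c(0, 1000)) {
  name <- match.arg(name)
  stopifnot(is.numeric(shift), length(shift) == 1L, is.finite(shift),
            length(psa_range) == 2L, psa_range[1] < psa_range[2])
  structure(list(name = name, shift = shift, psa_range = psa_range),
            class = "transform_spec")
}

#' Transform raw PSA to the modelling scale
#'
#' @param psa_raw Numeric vector of raw PSA values (ng/ml).
#' @param spec A [transform_spec()].
#' @return Transformed PSA (dimensionless), same length.
#' @export
transform_psa <- function(psa_raw, spec = transform_spec()) {
  stopifnot(inherits(spec, "transform_spec"), is.numeric(psa_raw))
  switch(spec$name,
    log_shift = {
      bad <- which(psa_raw <= -spec$shift)
      if (length(bad))
        stop("transform_psa: psa_raw must exceed -shift (", -spec$shift,
             "); offending value(s): ",
             paste(utils::head(psa_raw[bad], 5L), collapse = ", "))
      log(psa_raw + spec$shift)
    },
    sqrt = {
      bad <- which(psa_raw < 0)
      if (length(bad))
        stop("transform_psa: psa_raw must be >= 0 for sqrt; offending value(s): ",
             paste(utils::head(psa_raw[bad], 5L), collapse = ", "))
      sqrt(psa_raw)
    },
    identity = psa_raw
  )
}

#' Back-transform modelling-scale PSA to ng/ml
#'
#' Exact inverse of [transform_psa()] for the same spec.
#'
#' @inheritParams transform_psa
#' @param psa_star Transformed PSA values.
#' @return Raw PSA (ng/ml).
#' @export
inverse_transform_psa <- function(psa_star, spec = transform_spec()) {
  stopifnot(inherits(spec, "transform_spec"), is.numeric(psa_star))
  switch(spec$name,
    log_shift = exp(psa_star) - spec$shift,
    sqrt      = psa_star^2,
    identity  = psa_star
  )
}
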