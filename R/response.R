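#' Neuronal input-output response function
#'
#' The probability-of-activation nonlinearity `f(s)` mapping total synaptic
#' input to a value in \[0, 1\].  The default is the logistic sigmoid
#' `f(s) = 1 / (1 + exp(-s))`, for which the identity `f'(s) = f(s)(1 - f(s))`
#' holds exactly; this identity is what makes the two algebraic forms of the
#' linearized drift coefficients (see [lna_coefficients()]) agree, so the
#' logistic is the response function under which the fixed-point-substituted
#' coefficient formulas are exact.  A probit alternative (`pnorm(s)`) is
#' provided for sensitivity checks.
#'
#' @param s Input (any real vector).
#' @param kind `"logistic"` (default) or `"probit"`.
#' @param deriv If `TRUE`, return the derivative `f'(s)` instead.
#' @return Numeric vector in \[0, 1\] (or the derivative values).
#' @examples
#' response_function(0)            # 0.5
#' response_function(2, deriv = TRUE)
#' @export
response_function <- function(s, kind = c("logistic", "probit"), deriv = FALSE) {
  kind <- match.arg(kind)
  switch(kind,
    logistic = if (deriv) stats::plogis(s) * (1 - stats::plogis(s)) else stats::plogis(s),
    probit   = if (deriv) stats::dnorm(s) else stats::pnorm(s))
}
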