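#' Envelope-phase reduction: the two master parameters
#'
#' Reduces a linearized E-I fluctuation system to the parameters governing
#' the slow envelope and phase of its rhythm.  In the oscillatory regimes
#' the eigenvalues of the drift matrix are `-nu +/- i omega0` with damping
#' `nu = -(A11 + A22)/2` and angular peak frequency
#' `omega0 = sqrt(-(A11 - A22)^2 - 4 A12 A21) / 2`.  Stochastic averaging
#' of the narrowband fluctuations yields an envelope process
#' `dZ = (-nu Z + D/(2Z)) dt + sqrt(D) dW` with effective noise strength
#' `D = -(A12 / (2 omega0^2)) (-A12 sigma_I^2 + A21 sigma_E^2)`,
#' whose stationary density is Rayleigh with mode `R = sqrt(D / (2 nu))`.
#' Also returned are the mean inhibitory/excitatory envelope ratio
#' `alpha = sqrt(-A21 / A12)` and the mean E-I phase lag `delta`
#' (`arctan(2 omega0 / (A11 - A22))`, shifted by `pi` when
#' `A11 - A22 <= 0`, wrapped to `(-pi, pi]`).
#'
#' Regimes: `transient_synchrony` (complex eigenvalues, `nu > 0`; noise
#' sustains the rhythm), `high_synchrony` (complex, `nu <= 0`; oscillation
#' survives without noise), `asynchronous` (real eigenvalues, stable) and
#' `unstable` (real eigenvalues, positive growth rate).  Outside the
#' oscillatory regimes `omega0`, `D`, `R`, `alpha` and `delta` are `NA`.
#'
#' @param coeffs A [lna_coefficients()] object.
#' @return Object of class `wc_reduction`: list with `nu`, `omega0`
#'   (rad/ms), `freq_Hz` (`omega0/(2 pi) * 1000`), `D`, `R`, `alpha`,
#'   `delta`, `regime`, plus the coefficient set.
#' @examples
#' red <- reduce_lna(lna_coefficients(wc_params()))
#' c(red$nu, red$D, red$R)
#' @export
reduce_lna <- function(coeffs) {
  stopifnot(inherits(coeffs, "wc_lna"))
  A11 <- coeffs$A11; A12 <- coeffs$A12; A21 <- coeffs$A21; A22 <- coeffs$A22
  nu <- -(A11 + A22) / 2
  disc <- (A11 - A22)^2 + 4 * A12 * A21   # < 0 in the oscillatory regimes

  if (disc >= 0) {
    regime <- if (nu > 0) "asynchronous" else "unstable"
    out <- list(nu = nu, omega0 = NA_real_, freq_Hz = NA_real_,
                D = NA_real_, R = NA_real_, alpha = NA_real_,
                delta = NA_real_, regime = regime, coeffs = coeffs)
    return(structure(out, class = "wc_reduction"))
  }

  omega0 <- sqrt(-disc) / 2
  D <- -(A12 / (2 * omega0^2)) * (-A12 * coeffs$sigma_I^2 + A21 * coeffs$sigma_E^2)
  regime <- if (nu > 0) "transient_synchrony" else "high_synchrony"
  R <- if (nu > 0) sqrt(D / (2 * nu)) else NA_real_
  alpha <- sqrt(-A21 / A12)
  delta <- atan(2 * omega0 / (A11 - A22))
  if (A11 - A22 <= 0) delta <- delta + pi
  delta <- wrap_angle(delta)

  structure(list(nu = nu, omega0 = omega0,
                 freq_Hz = omega0 / (2 * pi) * 1000,
                 D = D, R = R, alpha = alpha, delta = delta,
                 regime = regime, coeffs = coeffs),
            class = "wc_reduction")
}

wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)
}

#' One-shot reduction from biophysical parameters
#'
#' Convenience pipeline [solve_fixed_point()] then [lna_coefficients()]
#' then [reduce_lna()].
#'
#' @param params A [wc_params()] object.
#' @param kind Response-function kind.
#' @return A `wc_reduction` object.
#' @examples
#' tidy(quasicycle(wc_point("a")))
#' @export
quasicycle <- function(params, kind = "logistic") {
  reduce_lna(lna_coefficients(params, kind = kind))
}

#' @export
print.wc_reduction <- function(x, ...) {
  cat("<wc_reduction> envelope-phase master parameters\n")
  cat(sprintf("  regime: %s\n", x$regime))
  cat(sprintf("  nu = %.5f per ms (damping time %.1f ms)\n", x$nu, 1 / abs(x$nu)))
  if (!is.na(x$omega0)) {
    cat(sprintf("  omega0 = %.5f rad/ms  (peak frequency %.1f Hz)\n",
                x$omega0, x$freq_Hz))
    cat(sprintf("  D = %.5f,  R = %s\n", x$D,
                if (is.na(x$R)) "NA" else sprintf("%.4f", x$R)))
    cat(sprintf("  envelope ratio alpha = %.4f, phase lag delta = %.4f rad\n",
                x$alpha, x$delta))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an envelope-phase reduction
#'
#' @param x A `wc_reduction` object.
#' @param ... Unused.
#' @return One-row tibble with columns `nu`, `omega0`, `freq_Hz`, `D`, `R`,
#'   `alpha`, `delta`, `regime`.
#' @export
tidy.wc_reduction <- function(x, ...) {
  tibble::tibble(nu = x$nu, omega0 = x$omega0, freq_Hz = x$freq_Hz,
                 D = x$D, R = x$R, alpha = x$alpha, delta = x$delta,
                 regime = x$regime)
}

#' @rdname tidy.wc_reduction
#' @export
glance.wc_reduction <- function(x, ...) {
  tibble::tibble(regime = x$regime, nu = x$nu, freq_Hz = x$freq_Hz, R = x$R,
                 damping_time_ms = 1 / abs(x$nu),
                 E0 = x$coeffs$fixed_point$E0, I0 = x$coeffs$fixed_point$I0)
}

#' Tidy a set of LNA coefficients
#' @param x A `wc_lna` object.
#' @param ... Unused.
#' @return One-row tibble of the seven coefficients and the fixed point.
#' @export
tidy.wc_lna <- function(x, ...) {
  tibble::tibble(A11 = x$A11, A12 = x$A12, A21 = x$A21, A22 = x$A22,
                 sigma_E = x$sigma_E, sigma_I = x$sigma_I, c_EI = x$c_EI,
                 E0 = x$fixed_point$E0, I0 = x$fixed_point$I0)
}
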