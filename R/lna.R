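#' Linear noise approximation coefficients
#'
#' Linearizes the stochastic Wilson-Cowan rate equations around the stable
#' fixed point and returns the seven quantities governing the fluctuation
#' (LFP) dynamics `dV_E = (A11 V_E + A12 V_I) dt + sigma_E dW_E` (and its
#' inhibitory analogue): the Jacobian entries `A11..A22` (per ms), the
#' noise intensities `sigma_E = sqrt(2 alpha_E E0)`,
#' `sigma_I = sqrt(2 alpha_I I0)` and the population-size ratio
#' `c_EI = sqrt(N_E / N_I)`.  Here `V_E = sqrt(N_E) (E - E0)` is the
#' system-size-scaled deviation of the excitatory activity (likewise for I),
#' so the additive noise intensities follow from the state-dependent
#' microscopic transition noise evaluated at the fixed point.
#'
#' Two algebraically equivalent forms of the drift entries are available:
#' the `"derivative"` form written with `f'(s)` and the `"substituted"` form
#' in which the fixed-point relation `f(s_E0) = alpha_E E0 / ((1-E0) beta_E)`
#' and the logistic identity `f' = f(1-f)` have been used to eliminate `f'`.
#' They agree (to machine precision) exactly when the response function is
#' logistic, which is why the logistic is the package default.
#'
#' @param params A [wc_params()] object.
#' @param fp A [solve_fixed_point()] result; solved afresh when omitted.
#' @param kind Response-function kind.
#' @param form `"derivative"` (default) or `"substituted"` algebraic form.
#' @return Object of class `wc_lna`: list with `A11`, `A12`, `A21`, `A22`,
#'   `sigma_E`, `sigma_I`, `c_EI`, the fixed point and the parameters.
#' @examples
#' cf <- lna_coefficients(wc_params())
#' cf$A12 < 0 && cf$A21 > 0
#' @export
lna_coefficients <- function(params, fp = solve_fixed_point(params, kind),
                             kind = "logistic",
                             form = c("derivative", "substituted")) {
  stopifnot(inherits(params, "wc_params"), inherits(fp, "wc_fixed_point"))
  form <- match.arg(form)
  p <- params
  E0 <- fp$E0; I0 <- fp$I0
  res <- max(abs(wc_field(p, E0, I0, kind)))
  if (res > 1e-8)
    stop(sprintf("supplied point is not a fixed point (residual %.3e)", res),
         call. = FALSE)
  c_EI <- sqrt(p$N_E / p$N_I)

  if (form == "derivative") {
    s <- wc_inputs(p, E0, I0)
    fE  <- response_function(s$s_E, kind); fI  <- response_function(s$s_I, kind)
    dfE <- response_function(s$s_E, kind, deriv = TRUE)
    dfI <- response_function(s$s_I, kind, deriv = TRUE)
    A11 <- -p$alpha_E - p$beta_E * fE + (1 - E0) * p$W_ee * p$beta_E * dfE
    A12 <- -(1 - E0) * p$W_ei * p$beta_E * dfE * c_EI
    A21 <- (1 - I0) * p$W_ie * p$beta_I * dfI / c_EI
    A22 <- -p$alpha_I - p$beta_I * fI - (1 - I0) * p$W_ii * p$beta_I * dfI
  } else {
    # fixed-point-substituted form; exact only for the logistic response
    gE <- p$alpha_E * E0 * (1 - p$alpha_E * E0 / ((1 - E0) * p$beta_E))
    gI <- p$alpha_I * I0 * (1 - p$alpha_I * I0 / ((1 - I0) * p$beta_I))
    A11 <- -p$alpha_E / (1 - E0) + gE * p$W_ee
    A12 <- -c_EI * gE * p$W_ei
    A21 <- gI * p$W_ie / c_EI
    A22 <- -p$alpha_I / (1 - I0) - gI * p$W_ii
  }

  structure(list(A11 = A11, A12 = A12, A21 = A21, A22 = A22,
                 sigma_E = sqrt(2 * p$alpha_E * E0),
                 sigma_I = sqrt(2 * p$alpha_I * I0),
                 c_EI = c_EI, fixed_point = fp, params = params, kind = kind),
            class = "wc_lna")
}

#' Drift matrix of an LNA coefficient set
#' @param coeffs A `wc_lna` object.
#' @return The 2x2 drift matrix `A`.
#' @export
lna_matrix <- function(coeffs) {
  stopifnot(inherits(coeffs, "wc_lna"))
  matrix(c(coeffs$A11, coeffs$A12, coeffs$A21, coeffs$A22), 2, 2, byrow = TRUE)
}

# Matrix exponential via eigendecomposition (robust for any t, unlike
# series-based routines on strongly rotating matrices).
expm_eig <- function(A, t = 1) {
  e <- eigen(A)
  Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
}

# Stationary covariance of the LNA: solves A S + S A' + diag(sE^2, sI^2) = 0.
lna_stationary_cov <- function(coeffs) {
  A <- lna_matrix(coeffs)
  Q <- diag(c(coeffs$sigma_E^2, coeffs$sigma_I^2))
  # vec form: (A (x) I + I (x) A) vec(S) = -vec(Q)
  K <- kronecker(A, diag(2)) + kronecker(diag(2), A)
  matrix(solve(K, -as.vector(Q)), 2, 2)
}

#' @export
print.wc_lna <- function(x, ...) {
  cat("<wc_lna> linearized fluctuation dynamics\n")
  cat(sprintf("  A = [% .5f % .5f; % .5f % .5f] per ms\n", x$A11, x$A12, x$A21, x$A22))
  cat(sprintf("  sigma_E = %.5f, sigma_I = %.5f, c_EI = %g\n",
              x$sigma_E, x$sigma_I, x$c_EI))
  invisible(x)
}
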