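# Deterministic Wilson-Cowan vector field and its Jacobian, shared by the
# fixed-point solver, the ODE oracle and the linearization.

wc_inputs <- function(p, E, I) {
  list(s_E = p$W_ee * E - p$W_ei * I + p$h_E,
       s_I = p$W_ie * E - p$W_ii * I + p$h_I)
}

wc_field <- function(p, E, I, kind = "logistic") {
  s <- wc_inputs(p, E, I)
  c(-p$alpha_E * E + (1 - E) * p$beta_E * response_function(s$s_E, kind),
    -p$alpha_I * I + (1 - I) * p$beta_I * response_function(s$s_I, kind))
}

wc_jacobian <- function(p, E, I, kind = "logistic") {
  s <- wc_inputs(p, E, I)
  fE  <- response_function(s$s_E, kind); fI  <- response_function(s$s_I, kind)
  dfE <- response_function(s$s_E, kind, deriv = TRUE)
  dfI <- response_function(s$s_I, kind, deriv = TRUE)
  matrix(c(
    -p$alpha_E - p$beta_E * fE + (1 - E) * p$beta_E * dfE * p$W_ee,
    -(1 - E) * p$beta_E * dfE * p$W_ei,
    (1 - I) * p$beta_I * dfI * p$W_ie,
    -p$alpha_I - p$beta_I * fI - (1 - I) * p$beta_I * dfI * p$W_ii
  ), 2, 2, byrow = TRUE)
}

newton_root <- function(p, start, kind, tol = 1e-12, maxit = 60) {
  y <- start
  for (i in seq_len(maxit)) {
    Fv <- wc_field(p, y[1], y[2], kind)
    J <- wc_jacobian(p, y[1], y[2], kind)
    step <- tryCatch(solve(J, Fv), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    y <- y - step
    if (any(!is.finite(y))) return(NULL)
    if (max(abs(step)) < tol) break
  }
  if (max(abs(wc_field(p, y[1], y[2], kind))) > 1e-10) return(NULL)
  y
}

#' Solve for the stationary population activities
#'
#' Finds the fixed point `(E0, I0)` of the deterministic Wilson-Cowan rate
#' equations, i.e. the root of
#' `0 = -alpha_E E0 + (1 - E0) beta_E f(s_E)` and its inhibitory analogue.
#' The reported solution is the one reached by forward integration of the
#' rate equations from `(0.1, 0.1)` (so that, under multistability, the
#' physically selected equilibrium is returned), polished by Newton
#' iteration with the analytic Jacobian.  All distinct roots located by a
#' multi-start Newton search over a coarse grid are exposed for diagnostics.
#'
#' @param params A [wc_params()] object.
#' @param kind Response-function kind passed to [response_function()].
#' @return An object of class `wc_fixed_point`: a list with elements
#'   `E0`, `I0`, `residual` (max absolute stationarity residual), and
#'   `roots`, a tibble of all distinct roots found.
#' @examples
#' fp <- solve_fixed_point(wc_params())
#' fp$E0
#' @export
solve_fixed_point <- function(params, kind = "logistic") {
  stopifnot(inherits(params, "wc_params"))
  p <- params

  # Degenerate case: activation switched off -> activities decay to zero.
  if (p$beta_E == 0 && p$beta_I == 0) {
    return(structure(list(E0 = 0, I0 = 0, residual = 0,
                          roots = tibble::tibble(E0 = 0, I0 = 0)),
                     class = "wc_fixed_point"))
  }

  rhs <- function(t, y, parms) list(wc_field(p, y[1], y[2], kind))
  traj <- deSolve::ode(c(E = 0.1, I = 0.1), c(0, 2500, 5000), rhs, NULL,
                       rtol = 1e-8, atol = 1e-10, maxsteps = 100000)
  y_ode <- as.numeric(traj[nrow(traj), 2:3])

  sel <- newton_root(p, y_ode, kind)
  if (is.null(sel)) {
    res <- max(abs(wc_field(p, y_ode[1], y_ode[2], kind)))
    stop(sprintf(paste0("fixed-point iteration failed to converge ",
                        "(last residual %.3e)"), res), call. = FALSE)
  }

  # multi-start sweep for additional roots
  grid <- expand.grid(E = c(0.02, 0.1, 0.3, 0.5, 0.7, 0.9),
                      I = c(0.02, 0.1, 0.3, 0.5, 0.7, 0.9))
  roots <- list(sel)
  for (i in seq_len(nrow(grid))) {
    r <- newton_root(p, as.numeric(grid[i, ]), kind)
    if (is.null(r)) next
    if (r[1] <= 0 || r[1] >= 1 || r[2] <= 0 || r[2] >= 1) next
    if (!any(vapply(roots, function(x) max(abs(x - r)) < 1e-8, logical(1))))
      roots <- c(roots, list(r))
  }
  roots_tbl <- tibble::tibble(E0 = vapply(roots, `[`, 0, 1),
                              I0 = vapply(roots, `[`, 0, 2))

  if (sel[1] <= 0 || sel[1] >= 1 || sel[2] <= 0 || sel[2] >= 1)
    stop("selected fixed point lies outside (0,1)^2", call. = FALSE)

  structure(list(E0 = sel[1], I0 = sel[2],
                 residual = max(abs(wc_field(p, sel[1], sel[2], kind))),
                 roots = roots_tbl),
            class = "wc_fixed_point")
}

#' @export
print.wc_fixed_point <- function(x, ...) {
  cat(sprintf("<wc_fixed_point> E0 = %.6f, I0 = %.6f (residual %.2e, %d root%s found)\n",
              x$E0, x$I0, x$residual, nrow(x$roots),
              if (nrow(x$roots) == 1) "" else "s"))
  invisible(x)
}
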