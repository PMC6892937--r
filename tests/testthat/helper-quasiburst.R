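# Shared fixtures: reductions at the four working points are deterministic
# and cheap, computed once per test run.

point_reductions <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lapply(setNames(nm = c("a", "b", "c", "d")),
                       function(pt) quasicycle(wc_point(pt)))
    cache
  }
})

# Effective number of independent samples of a series whose correlation
# time is tau (ms), sampled every dt (ms).
n_effective <- function(n, dt, tau) n * dt / (2 * tau)

# Build a wc_lna object directly from a drift matrix and noise intensities
# (for synthetic linear-systems tests).
fake_lna <- function(A, sigma_E, sigma_I, c_EI = 1) {
  structure(list(A11 = A[1, 1], A12 = A[1, 2], A21 = A[2, 1], A22 = A[2, 2],
                 sigma_E = sigma_E, sigma_I = sigma_I, c_EI = c_EI,
                 fixed_point = NULL, params = NULL, kind = "logistic"),
            class = "wc_lna")
}

# Random valid parameter draws in the neighbourhood of the default set,
# filtered to those whose fixed point solves cleanly.
random_params <- function(n, seed) {
  set.seed(seed)
  out <- list()
  while (length(out) < n) {
    p <- tryCatch(
      wc_params(alpha_E = runif(1, 0.05, 0.3), alpha_I = runif(1, 0.1, 0.4),
                beta_E = runif(1, 0.5, 2), beta_I = runif(1, 1, 3),
                h_E = runif(1, -6, -2), h_I = runif(1, -9, -4),
                W_ee = runif(1, 10, 30), W_ii = runif(1, 0.5, 5),
                W_ei = runif(1, 15, 30), W_ie = runif(1, 20, 40)),
      error = function(e) NULL)
    if (is.null(p)) next
    fp <- tryCatch(solve_fixed_point(p), error = function(e) NULL)
    if (is.null(fp)) next
    out[[length(out) + 1L]] <- list(params = p, fp = fp)
  }
  out
}
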