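test_that("pure death process decays and holding times average 1/alpha", {
  p <- wc_params(beta_E = 0, beta_I = 0, N_E = 300, N_I = 100)
  out <- simulate_gillespie(p, duration = 400, seed = 7, burn_in = 0,
                            init = c(300, 100), record_raster = TRUE)
  act <- out$activity
  expect_true(attr(act, "absorbed"))
  expect_equal(act$E[nrow(act)], 0)
  expect_equal(act$I[nrow(act)], 0)
  # every neuron starts active; its single off event time is its holding time
  offs <- out$raster[out$raster$population == "E" & out$raster$event == "off", ]
  expect_equal(nrow(offs), 300)
  m <- mean(offs$time)
  expect_lt(abs(m - 1 / p$alpha_E), 3 * (1 / p$alpha_E) / sqrt(300))
})

test_that("Gillespie mean activity agrees with the deterministic fixed point", {
  p <- wc_params()
  fp <- solve_fixed_point(p)
  red <- quasicycle(p)
  tr <- simulate_gillespie(p, duration = 20e3, seed = 11)
  # fluctuation scale / correlation time give the Monte-Carlo error
  sd_E <- sd(tr$E)
  neff <- n_effective(nrow(tr), attr(tr, "dt"), 1 / red$nu)
  expect_lt(abs(mean(tr$E) - fp$E0), 4 * sd_E / sqrt(neff) + 0.005)
  # transient synchrony: envelope strongly modulated (high/low epochs);
  # a Rayleigh-like envelope has coefficient of variation ~ 0.52
  lfp <- make_lfp(tr, "E", scale = sqrt(p$N_E))
  env <- analytic_signal(lfp)$envelope
  expect_gt(sd(env) / mean(env), 0.3)
})

test_that("simulators are deterministic given a seed", {
  p <- wc_params(N_E = 200, N_I = 50)
  a <- simulate_gillespie(p, duration = 500, seed = 5, burn_in = 50)
  b <- simulate_gillespie(p, duration = 500, seed = 5, burn_in = 50)
  expect_identical(a, b)
  c1 <- simulate_rate_sde(p, duration = 500, dt = 0.05, seed = 5, burn_in = 50)
  c2 <- simulate_rate_sde(p, duration = 500, dt = 0.05, seed = 5, burn_in = 50)
  expect_identical(c1, c2)
  cf <- lna_coefficients(p)
  d1 <- simulate_lna(cf, duration = 500, seed = 5)
  d2 <- simulate_lna(cf, duration = 500, seed = 5)
  expect_identical(d1, d2)
  red <- quasicycle(p)
  e1 <- simulate_sam(red, duration = 500, seed = 5)
  e2 <- simulate_sam(red, duration = 500, seed = 5)
  expect_identical(e1, e2)
})

test_that("noise-free rate equations converge to the fixed point", {
  p <- wc_params()
  fp <- solve_fixed_point(p)
  tr <- simulate_rate_sde(p, duration = 100, dt = 0.01, seed = 1,
                          burn_in = 3000, noise = FALSE)
  expect_equal(tail(tr$E, 1), fp$E0, tolerance = 1e-6)
  expect_equal(tail(tr$I, 1), fp$I0, tolerance = 1e-6)
})

test_that("microscopic and rate-SDE fluctuations agree (level-crossing consistency)", {
  p <- wc_params()
  red <- quasicycle(p)
  g <- simulate_gillespie(p, duration = 15e3, seed = 21)
  s <- simulate_rate_sde(p, duration = 15e3, dt = 0.02, seed = 22)
  tau <- 1 / red$nu
  ng <- n_effective(nrow(g), attr(g, "dt"), tau)
  ns <- n_effective(nrow(s), attr(s, "dt"), tau)
  se_mean <- sqrt(sd(g$E)^2 / ng + sd(s$E)^2 / ns)
  expect_lt(abs(mean(g$E) - mean(s$E)), 3 * se_mean)
  se_var <- sqrt(2) * sqrt(var(g$E)^2 / ng + var(s$E)^2 / ns)
  expect_lt(abs(var(g$E) - var(s$E)), 3 * se_var)
})

test_that("single-neuron firing is Poisson-like in transient synchrony", {
  p <- wc_params(N_E = 200, N_I = 50)   # smaller net, same rates/regime
  out <- simulate_gillespie(p, duration = 20e3, seed = 31, burn_in = 500,
                            record_raster = TRUE)
  ras <- out$raster
  ons <- ras[ras$population == "E" & ras$event == "on", ]
  cvs <- vapply(split(ons$time, ons$neuron), function(tt) {
    if (length(tt) < 20) return(NA_real_)
    iv <- diff(sort(tt))
    sd(iv) / mean(iv)
  }, 0)
  cvs <- cvs[!is.na(cvs)]
  expect_gt(length(cvs), 50)
  expect_lt(abs(mean(cvs) - 1), 0.25)
})

test_that("LNA stationary covariance matches the Lyapunov solution", {
  cf <- lna_coefficients(wc_params())
  red <- reduce_lna(cf)
  S <- quasiburst:::lna_stationary_cov(cf)
  tr <- simulate_lna(cf, duration = 60e3, dt = 0.5, seed = 41)
  tau <- 1 / red$nu
  neff <- n_effective(nrow(tr), 0.5, tau)
  for (pair in list(c("V_E", 1), c("V_I", 2))) {
    v <- tr[[pair[1]]]
    i <- as.integer(pair[2])
    expect_lt(abs(var(v) - S[i, i]), 3 * sqrt(2 / neff) * S[i, i])
  }
  # Euler scheme agrees with the exact scheme at small dt
  tre <- simulate_lna(cf, duration = 20e3, dt = 0.02, seed = 42,
                      method = "euler")
  expect_lt(abs(var(tre$V_E) - S[1, 1]),
            4 * sqrt(2 / n_effective(nrow(tre), 0.02, tau)) * S[1, 1])
})

test_that("noise-free LNA decays as a damped oscillation at (nu, omega0)", {
  cf <- lna_coefficients(wc_params())
  red <- reduce_lna(cf)
  cf0 <- cf
  cf0$sigma_E <- 0; cf0$sigma_I <- 0
  tr <- simulate_lna(cf0, duration = 300, dt = 0.1, seed = 1, burn_in = 0,
                     init = c(1, 0))
  # independent oracle: diagonalize A and propagate analytically
  A <- lna_matrix(cf)
  ev <- eigen(A)
  propagate <- function(t) {
    Re(ev$vectors %*% diag(exp(ev$values * t)) %*% solve(ev$vectors)) %*% c(1, 0)
  }
  expected <- t(vapply(tr$time, function(t) as.numeric(propagate(t)), c(0, 0)))
  expect_lt(max(abs(tr$V_E - expected[, 1])), 1e-6)
  # amplitude at one damping time has shrunk by about exp(-1)
  i <- which.min(abs(tr$time - 1 / red$nu))
  env <- sqrt(tr$V_E^2 + tr$V_I^2)
  expect_lt(env[i], 1)
})

test_that("SAM components are stationary OU processes with sd R", {
  red <- point_reductions()$b
  tr <- simulate_sam(red, duration = 150e3, dt = 0.5, seed = 51)
  tau <- 1 / red$nu
  neff <- n_effective(nrow(tr), 0.5, tau)
  for (col in c("E1", "E2")) {
    expect_lt(abs(sd(tr[[col]]) - red$R), 3 * red$R / sqrt(2 * neff) + 0.01)
  }
  # envelope follows the Rayleigh law of the reduction
  law <- as_envelope_law(red)
  ks <- suppressWarnings(
    stats::ks.test(tr$Z, function(q) stationary_cdf(q, law))$statistic)
  expect_lt(ks, 0.02)
  # reconstruction: V_E = Z cos(omega0 t + phi)
  expect_equal(tr$V_E, tr$Z * cos(red$omega0 * tr$time + tr$phi),
               tolerance = 1e-12)
})

test_that("SAM refuses non-oscillatory or undamped regimes", {
  bad <- structure(list(nu = -0.01, omega0 = 0.5, D = 0.05, R = NA,
                        alpha = 1, delta = 1, regime = "high_synchrony",
                        coeffs = NULL), class = "wc_reduction")
  expect_error(simulate_sam(bad, duration = 100), "transient-synchrony")
  expect_error(reduction_from_master(nu = -0.01, D = 0.05, omega0 = 0.5))
})
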