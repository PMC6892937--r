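test_that("logistic response matches direct arithmetic and its derivative identity", {
  for (s in c(-3.8, -8, 2.1)) {
    expect_equal(response_function(s), 1 / (1 + exp(-s)), tolerance = 1e-14)
  }
  expect_equal(response_function(0), 0.5)
  s <- seq(-10, 10, by = 0.37)
  expect_equal(response_function(s, deriv = TRUE),
               response_function(s) * (1 - response_function(s)),
               tolerance = 1e-14)
  expect_true(all(diff(response_function(s)) >= 0))
  expect_true(all(response_function(s) >= 0 & response_function(s) <= 1))
  expect_error(response_function(0, kind = "heaviside"))
})

test_that("parameter validation rejects malformed sets and configs round-trip", {
  expect_error(wc_params(alpha_E = -0.1), "positive")
  expect_error(wc_params(W_ee = -1), "non-negative")
  expect_error(wc_params(N_E = 0.5), "positive integer")
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_params(wc_params(W_ee = 22.2), tmp)
  expect_equal(read_params(tmp)$W_ee, 22.2)
  tmp2 <- withr::local_tempfile(fileext = ".json")
  write_params(wc_params(), tmp2)
  expect_equal(unclass(read_params(tmp2)), unclass(wc_params()))
  shipped <- system.file("extdata", "table1.yaml", package = "quasiburst")
  expect_equal(unclass(read_params(shipped)), unclass(wc_params()))
  tmp3 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(W_ee = 20, bogus = 1), tmp3)
  expect_error(read_params(tmp3), "unknown parameter")
})

test_that("fixed point: activation off gives the origin, otherwise matches the ODE limit", {
  fp0 <- solve_fixed_point(wc_params(beta_E = 0, beta_I = 0))
  expect_equal(c(fp0$E0, fp0$I0), c(0, 0))

  p <- wc_params()
  fp <- solve_fixed_point(p)
  expect_lt(fp$residual, 1e-10)
  expect_true(fp$E0 > 0 && fp$E0 < 1 && fp$I0 > 0 && fp$I0 < 1)

  # independent oracle: long forward integration of the rate ODEs
  f <- function(s) 1 / (1 + exp(-s))
  rhs <- function(t, y, parms) {
    sE <- p$W_ee * y[1] - p$W_ei * y[2] + p$h_E
    sI <- p$W_ie * y[1] - p$W_ii * y[2] + p$h_I
    list(c(-p$alpha_E * y[1] + (1 - y[1]) * p$beta_E * f(sE),
           -p$alpha_I * y[2] + (1 - y[2]) * p$beta_I * f(sI)))
  }
  lim <- deSolve::ode(c(0.1, 0.1), seq(0, 8000, 4000), rhs, NULL,
                      rtol = 1e-10, atol = 1e-12, maxsteps = 1e6)
  expect_equal(c(fp$E0, fp$I0), as.numeric(lim[nrow(lim), 2:3]),
               tolerance = 1e-6)
})

test_that("derivative and substituted coefficient forms agree under the logistic response", {
  draws <- random_params(6, seed = 42)
  for (d in draws) {
    c1 <- lna_coefficients(d$params, d$fp, form = "derivative")
    c2 <- lna_coefficients(d$params, d$fp, form = "substituted")
    expect_equal(c(c1$A11, c1$A12, c1$A21, c1$A22),
                 c(c2$A11, c2$A12, c2$A21, c2$A22), tolerance = 1e-10)
    expect_lt(c1$A12, 0)
    expect_gt(c1$A21, 0)
  }
})

test_that("coefficients at the default set: population ratio and noise intensities", {
  cf <- lna_coefficients(wc_params())
  expect_equal(cf$c_EI, 2)
  expect_equal(cf$sigma_E, sqrt(2 * 0.1 * cf$fixed_point$E0))
  expect_equal(cf$sigma_I, sqrt(2 * 0.2 * cf$fixed_point$I0))
  fp_bad <- structure(list(E0 = 0.5, I0 = 0.5, residual = 1,
                           roots = NULL), class = "wc_fixed_point")
  expect_error(lna_coefficients(wc_params(), fp_bad), "not a fixed point")
})

test_that("reduction is eigen-consistent and satisfies the R identity", {
  for (red in point_reductions()) {
    ev <- eigen(lna_matrix(red$coeffs))$values
    expect_equal(Re(ev), rep(-red$nu, 2), tolerance = 1e-10)
    expect_equal(sort(Im(ev)), c(-red$omega0, red$omega0), tolerance = 1e-10)
    expect_equal(red$R^2 * 2 * red$nu, red$D, tolerance = 1e-12)
    expect_identical(red$regime, "transient_synchrony")
    expect_true(red$delta > -pi && red$delta <= pi)
  }
})

test_that("rotation-symmetric drift reduces to its own (nu, omega)", {
  nu0 <- 0.05; om <- 0.6; sig <- 0.3
  red <- reduce_lna(fake_lna(matrix(c(-nu0, -om, om, -nu0), 2, byrow = TRUE),
                             sig, sig))
  expect_equal(red$nu, nu0, tolerance = 1e-12)
  expect_equal(red$omega0, om, tolerance = 1e-12)
  # D reduces to sigma^2 in this symmetric case
  expect_equal(red$D, sig^2, tolerance = 1e-12)
  expect_equal(red$R, sqrt(sig^2 / (2 * nu0)), tolerance = 1e-12)
})

test_that("phase-lag branch rule adds pi when A11 - A22 <= 0", {
  A <- matrix(c(-0.3, -0.5, 0.5, -0.1), 2, byrow = TRUE)  # A11 - A22 < 0
  red <- reduce_lna(fake_lna(A, 0.2, 0.2))
  raw <- atan(2 * red$omega0 / (A[1, 1] - A[2, 2]))
  expect_equal(red$delta, raw + pi, tolerance = 1e-12)
  B <- matrix(c(-0.1, -0.5, 0.5, -0.3), 2, byrow = TRUE)  # A11 - A22 > 0
  red2 <- reduce_lna(fake_lna(B, 0.2, 0.2))
  expect_equal(red2$delta, atan(2 * red2$omega0 / (B[1, 1] - B[2, 2])),
               tolerance = 1e-12)
})

test_that("damping decreases and synchrony grows along the W_ee sweep", {
  reds <- point_reductions()
  nus <- vapply(reds, `[[`, 0, "nu")
  Rs <- vapply(reds, `[[`, 0, "R")
  fs <- vapply(reds, `[[`, 0, "freq_Hz")
  expect_true(all(diff(nus) < 0))
  expect_true(all(diff(Rs) > 0))
  expect_true(all(fs > 55 & fs < 100))   # gamma-band rhythm throughout
})

test_that("regime map labels cells and brackets the Hopf transition", {
  m <- regime_map(wc_params(), "W_ee", c(20.4, 29.4, 31.5), "W_ii", c(1.3))
  expect_s3_class(m, "tbl_df")
  expect_identical(m$regime[m$W_ee == 20.4], "transient_synchrony")
  expect_identical(m$regime[m$W_ee == 29.4], "transient_synchrony")
  expect_identical(m$regime[m$W_ee == 31.5], "high_synchrony")
  expect_lt(m$nu[m$W_ee == 31.5], 0)

  # bisection on the damping along the same sweep
  wc_crit <- find_transition(wc_params(), "W_ee", c(29.4, 31.5), tol = 1e-7)
  expect_true(wc_crit > 29.4 && wc_crit < 31.5)
  p <- wc_params(); p$W_ee <- wc_crit
  expect_lt(abs(quasicycle(do.call(wc_params, unclass(p)))$nu), 1e-5)

  # weak coupling: no oscillation, stable node -> asynchronous
  m2 <- regime_map(wc_params(), "W_ei", c(0.1), "W_ie", c(0.1))
  expect_identical(m2$regime, "asynchronous")
  expect_true(is.na(m2$omega0_Hz))
})
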