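# All simulators are pure functions of (parameters, duration, dt, seed):
# a fixed seed gives bit-identical traces.  Times are in ms throughout.

trace_dt <- function(x, time = "time") {
  stopifnot(is.data.frame(x), time %in% names(x), nrow(x) >= 2)
  stats::median(diff(x[[time]]))
}

#' Exact Gillespie simulation of the microscopic two-state network
#'
#' Simulates the aggregate Markov chain over the active counts `(k, l)` of
#' the fully connected network of `N_E` excitatory and `N_I` inhibitory
#' two-state neurons, using the exact stochastic simulation algorithm with
#' four reaction channels: `k -> k - 1` at rate `k alpha_E`;
#' `k -> k + 1` at rate `(N_E - k) beta_E f(s_E)`; and the analogous
#' inhibitory channels, with the synaptic inputs
#' `s_E = W_ee k / N_E - W_ei l / N_I + h_E` (likewise `s_I`).  Because the
#' network is homogeneous and all-to-all, the aggregate chain is an exact
#' representation of the per-neuron dynamics; a per-neuron spike raster can
#' be reconstructed by assigning each aggregate event to a uniformly chosen
#' eligible neuron (exchangeability).
#'
#' The jump process is resampled onto a uniform grid by zero-order hold.
#' The chain starts at the rounded deterministic fixed point and the first
#' `burn_in` ms are discarded.
#'
#' @param params A [wc_params()] object.
#' @param duration Recorded duration (ms) after burn-in.
#' @param seed Integer RNG seed.
#' @param dt_out Output sampling interval (ms); default 0.5 ms, comfortably
#'   above the Nyquist requirement for a 100 Hz band edge.
#' @param record_raster If `TRUE`, also return per-neuron activation /
#'   deactivation events (slower).
#' @param burn_in Discarded initial span (ms).
#' @param init Optional starting counts `c(k, l)`; defaults to the rounded
#'   fixed point.
#' @param kind Response-function kind.
#' @return A tibble with columns `time`, `E`, `I` (activities in \[0, 1\]).
#'   Attributes: `seed`, `dt`, `absorbed` (TRUE if the chain hit a state of
#'   zero total rate and ended early).  With `record_raster = TRUE`, a
#'   list with elements `activity` (the tibble) and `raster` (tibble with
#'   `time`, `neuron`, `population`, `event`).
#' @examples
#' tr <- simulate_gillespie(wc_params(N_E = 80, N_I = 20), duration = 200,
#'                          seed = 1, burn_in = 50)
#' @export
simulate_gillespie <- function(params, duration, seed, dt_out = 0.5,
                               record_raster = FALSE, burn_in = 500,
                               init = NULL, kind = "logistic") {
  stopifnot(inherits(params, "wc_params"), duration > 0, dt_out > 0)
  p <- params
  set.seed(seed)
  NE <- as.integer(p$N_E); NI <- as.integer(p$N_I)

  if (is.null(init)) {
    fp <- tryCatch(solve_fixed_point(p, kind), error = function(e) NULL)
    init <- if (is.null(fp)) c(round(0.1 * NE), round(0.1 * NI))
            else c(round(fp$E0 * NE), round(fp$I0 * NI))
  }
  k <- as.integer(init[1]); l <- as.integer(init[2])

  t_end <- burn_in + duration
  grid <- seq(0, t_end, by = dt_out)
  n_grid <- length(grid)
  kk <- integer(n_grid); ll <- integer(n_grid)
  gi <- 1L

  if (record_raster) {
    state_E <- c(rep(TRUE, k), rep(FALSE, NE - k))
    state_I <- c(rep(TRUE, l), rep(FALSE, NI - l))
    ev_cap <- 65536L; ev_len <- 0L
    ev_t <- numeric(ev_cap); ev_n <- integer(ev_cap)
    ev_pop <- character(ev_cap); ev_e <- character(ev_cap)
    push_event <- function(tm, who, pop, e) {
      if (ev_len == ev_cap) {
        ev_cap <<- 2L * ev_cap
        length(ev_t) <<- ev_cap; length(ev_n) <<- ev_cap
        length(ev_pop) <<- ev_cap; length(ev_e) <<- ev_cap
      }
      ev_len <<- ev_len + 1L
      ev_t[ev_len] <<- tm; ev_n[ev_len] <<- who
      ev_pop[ev_len] <<- pop; ev_e[ev_len] <<- e
    }
  }

  # block-refilled uniforms: one for waiting times, one for channel choice
  nbuf <- 100000L
  u1 <- stats::runif(nbuf); u2 <- stats::runif(nbuf); bi <- 0L

  t <- 0
  absorbed <- FALSE
  logistic <- identical(kind, "logistic")
  repeat {
    s_E <- p$W_ee * k / NE - p$W_ei * l / NI + p$h_E
    s_I <- p$W_ie * k / NE - p$W_ii * l / NI + p$h_I
    fE <- if (logistic) 1 / (1 + exp(-s_E)) else response_function(s_E, kind)
    fI <- if (logistic) 1 / (1 + exp(-s_I)) else response_function(s_I, kind)
    r1 <- k * p$alpha_E
    r2 <- (NE - k) * p$beta_E * fE
    r3 <- l * p$alpha_I
    r4 <- (NI - l) * p$beta_I * fI
    rtot <- r1 + r2 + r3 + r4
    if (rtot <= 0) { absorbed <- TRUE; break }

    bi <- bi + 1L
    if (bi > nbuf) { u1 <- stats::runif(nbuf); u2 <- stats::runif(nbuf); bi <- 1L }
    t_next <- t - log(u1[bi]) / rtot

    # zero-order hold: state (k, l) persists on [t, t_next)
    while (gi <= n_grid && grid[gi] < t_next) {
      kk[gi] <- k; ll[gi] <- l; gi <- gi + 1L
    }
    if (gi > n_grid) break
    t <- t_next
    x <- u2[bi] * rtot
    if (x < r1) {
      if (record_raster) {
        who <- which(state_E); who <- who[sample.int(length(who), 1L)]
        state_E[who] <- FALSE
        push_event(t, who, "E", "off")
      }
      k <- k - 1L
    } else if (x < r1 + r2) {
      if (record_raster) {
        who <- which(!state_E); who <- who[sample.int(length(who), 1L)]
        state_E[who] <- TRUE
        push_event(t, who, "E", "on")
      }
      k <- k + 1L
    } else if (x < r1 + r2 + r3) {
      if (record_raster) {
        who <- which(state_I); who <- who[sample.int(length(who), 1L)]
        state_I[who] <- FALSE
        push_event(t, who, "I", "off")
      }
      l <- l - 1L
    } else {
      if (record_raster) {
        who <- which(!state_I); who <- who[sample.int(length(who), 1L)]
        state_I[who] <- TRUE
        push_event(t, who, "I", "on")
      }
      l <- l + 1L
    }
  }
  if (absorbed && gi <= n_grid) {  # hold the absorbing state to the end
    kk[gi:n_grid] <- k; ll[gi:n_grid] <- l
  }

  keep <- grid >= burn_in
  out <- tibble::tibble(time = grid[keep] - burn_in,
                        E = kk[keep] / NE, I = ll[keep] / NI)
  attr(out, "dt") <- dt_out
  attr(out, "seed") <- seed
  attr(out, "absorbed") <- absorbed
  if (!record_raster) return(out)
  idx <- seq_len(ev_len)
  raster <- tibble::tibble(time = ev_t[idx] - burn_in, neuron = ev_n[idx],
                           population = ev_pop[idx], event = ev_e[idx])
  list(activity = out, raster = raster)
}

#' Euler-Maruyama integration of the stochastic Wilson-Cowan rate equations
#'
#' Integrates the nonlinear rate SDEs
#' `dE = (-alpha_E E + (1 - E) beta_E f(s_E)) dt + g_E dW_E` with the
#' state-dependent (system-size) noise amplitude
#' `g_E = sqrt(((1 - E) beta_E f(s_E) + alpha_E E) / N_E)` and the analogous
#' inhibitory equation.  Trajectories are clipped to \[0, 1\]; the fraction
#' of clipped steps is recorded and a warning is raised if it exceeds 0.1%.
#'
#' @param params A [wc_params()] object.
#' @param duration Recorded duration (ms) after burn-in.
#' @param dt Integration step (ms); default 0.01.
#' @param seed Integer RNG seed.
#' @param dt_out Output sampling interval (ms), a multiple of `dt`.
#' @param burn_in Discarded initial span (ms).
#' @param noise If `FALSE`, integrate the deterministic rate equations
#'   (the infinite-size limit).
#' @param kind Response-function kind.
#' @return Tibble with columns `time`, `E`, `I`; attributes `dt`, `seed`,
#'   `clip_fraction`.
#' @export
simulate_rate_sde <- function(params, duration, dt = 0.01, seed = 1,
                              dt_out = 0.5, burn_in = 500, noise = TRUE,
                              kind = "logistic") {
  stopifnot(inherits(params, "wc_params"), duration > 0, dt > 0)
  p <- params
  set.seed(seed)
  thin <- max(1L, round(dt_out / dt))
  dt_out <- thin * dt
  n_steps <- ceiling((burn_in + duration) / dt)
  n_out <- floor(n_steps / thin) + 1L

  fp <- solve_fixed_point(p, kind)
  E <- fp$E0; I <- fp$I0
  Eo <- numeric(n_out); Io <- numeric(n_out)
  Eo[1] <- E; Io[1] <- I
  oi <- 1L

  sqdt <- sqrt(dt)
  nbuf <- 100000L
  zE <- stats::rnorm(nbuf); zI <- stats::rnorm(nbuf); bi <- 0L
  clipped <- 0L
  logistic <- identical(kind, "logistic")

  for (i in seq_len(n_steps)) {
    s_E <- p$W_ee * E - p$W_ei * I + p$h_E
    s_I <- p$W_ie * E - p$W_ii * I + p$h_I
    fE <- if (logistic) 1 / (1 + exp(-s_E)) else response_function(s_E, kind)
    fI <- if (logistic) 1 / (1 + exp(-s_I)) else response_function(s_I, kind)
    aE <- (1 - E) * p$beta_E * fE
    aI <- (1 - I) * p$beta_I * fI
    drift_E <- -p$alpha_E * E + aE
    drift_I <- -p$alpha_I * I + aI
    if (noise) {
      bi <- bi + 1L
      if (bi > nbuf) { zE <- stats::rnorm(nbuf); zI <- stats::rnorm(nbuf); bi <- 1L }
      E <- E + drift_E * dt + sqrt((aE + p$alpha_E * E) / p$N_E) * sqdt * zE[bi]
      I <- I + drift_I * dt + sqrt((aI + p$alpha_I * I) / p$N_I) * sqdt * zI[bi]
    } else {
      E <- E + drift_E * dt
      I <- I + drift_I * dt
    }
    if (E < 0 || E > 1 || I < 0 || I > 1) {
      clipped <- clipped + 1L
      E <- min(max(E, 0), 1); I <- min(max(I, 0), 1)
    }
    if (i %% thin == 0L) {
      oi <- oi + 1L
      Eo[oi] <- E; Io[oi] <- I
    }
  }

  clip_fraction <- clipped / n_steps
  if (clip_fraction > 0.001)
    warning(sprintf("%.2f%% of steps clipped to [0,1]", 100 * clip_fraction))

  tt <- (seq_len(oi) - 1L) * dt_out
  keep <- tt >= burn_in
  out <- tibble::tibble(time = tt[keep] - burn_in, E = Eo[seq_len(oi)][keep],
                        I = Io[seq_len(oi)][keep])
  attr(out, "dt") <- dt_out
  attr(out, "seed") <- seed
  attr(out, "clip_fraction") <- clip_fraction
  out
}

#' Simulate the linear noise approximation
#'
#' Integrates the linear fluctuation SDEs
#' `dV = A V dt + diag(sigma_E, sigma_I) dW`.  The default integrator is
#' the exact Gaussian one-step scheme (`V[n+1] = M V[n] + w[n]` with
#' `M = expm(A dt)` and innovation covariance equal to the exact discrete
#' Lyapunov increment), which samples the true transition kernel at any
#' step size; an Euler-Maruyama scheme is available for cross-checks.
#'
#' @param coeffs A [lna_coefficients()] object.
#' @param duration Recorded duration (ms) after burn-in.
#' @param dt Step (ms): default 0.5 for `"exact"`, use ~0.01 for `"euler"`.
#' @param seed Integer RNG seed.
#' @param method `"exact"` (default) or `"euler"`.
#' @param burn_in Discarded initial span (ms).
#' @param init Initial `c(V_E, V_I)`; default `c(0, 0)`.
#' @return Tibble with columns `time`, `V_E`, `V_I`; attributes `dt`, `seed`.
#' @export
simulate_lna <- function(coeffs, duration, dt = 0.5, seed = 1,
                         method = c("exact", "euler"), burn_in = 500,
                         init = c(0, 0)) {
  stopifnot(inherits(coeffs, "wc_lna"), duration > 0, dt > 0)
  method <- match.arg(method)
  set.seed(seed)
  A <- lna_matrix(coeffs)
  nu <- -(A[1, 1] + A[2, 2]) / 2
  if (nu <= 0 && duration > 100)
    warning("drift matrix is unstable (nu <= 0); trajectories will diverge")

  n_steps <- ceiling((burn_in + duration) / dt)
  V <- matrix(0, 2, n_steps + 1L)
  V[, 1] <- init

  if (method == "exact") {
    M <- expm_eig(A, dt)
    S <- lna_stationary_cov(coeffs)
    Q <- (S - M %*% S %*% t(M) + t(S - M %*% S %*% t(M))) / 2
    L <- if (max(abs(Q)) == 0) matrix(0, 2, 2) else t(chol(Q))
    W <- L %*% matrix(stats::rnorm(2 * n_steps), 2)
    for (i in seq_len(n_steps)) V[, i + 1L] <- M %*% V[, i] + W[, i]
  } else {
    sq <- sqrt(dt)
    W <- matrix(stats::rnorm(2 * n_steps), 2) * c(coeffs$sigma_E, coeffs$sigma_I) * sq
    Mdt <- diag(2) + A * dt
    for (i in seq_len(n_steps)) V[, i + 1L] <- Mdt %*% V[, i] + W[, i]
  }

  tt <- (0:n_steps) * dt
  keep <- tt >= burn_in
  out <- tibble::tibble(time = tt[keep] - burn_in,
                        V_E = V[1, keep], V_I = V[2, keep])
  attr(out, "dt") <- dt
  attr(out, "seed") <- seed
  out
}

#' Simulate the envelope-phase reduction via its Ornstein-Uhlenbeck pair
#'
#' The stochastic-averaging envelope and phase satisfy
#' `dZ = (-nu Z + D/(2Z)) dt + sqrt(D) dW1`,
#' `dphi = sqrt(D)/Z dW2`.  They are generated here through the equivalent
#' representation as the modulus and angle of two independent OU processes
#' `dE_j = -nu E_j dt + sqrt(D) dW_j`, which avoids the numerical
#' possibility of a negative envelope near `Z = 0`.  Each OU component is
#' advanced with its exact Gaussian transition (no discretization bias) and
#' initialized from its stationary law, so no burn-in is required by
#' default.  The associated excitatory and inhibitory LFPs are
#' reconstructed as `V_E = Z cos(omega0 t + phi)` and
#' `V_I = alpha Z cos(omega0 t + phi - delta)`.
#'
#' @param reduction A [reduce_lna()] / [quasicycle()] result with `nu > 0`.
#' @param duration Recorded duration (ms).
#' @param dt Sampling step (ms); default 0.1.
#' @param seed Integer RNG seed.
#' @param burn_in Discarded initial span (ms); default 0 (stationary start).
#' @return Tibble with columns `time`, `E1`, `E2`, `Z` (envelope), `phi`
#'   (wrapped phase, rad), `V_E`, `V_I`; attributes `dt`, `seed`.
#' @examples
#' red <- quasicycle(wc_point("b"))
#' tr <- simulate_sam(red, duration = 1000, seed = 1)
#' @export
simulate_sam <- function(reduction, duration, dt = 0.1, seed = 1,
                         burn_in = 0) {
  stopifnot(inherits(reduction, "wc_reduction"), duration > 0, dt > 0)
  if (is.na(reduction$nu) || reduction$nu <= 0 || is.na(reduction$D))
    stop("stochastic averaging requires the transient-synchrony regime (nu > 0)",
         call. = FALSE)
  nu <- reduction$nu; D <- reduction$D
  set.seed(seed)
  n <- ceiling((burn_in + duration) / dt) + 1L
  R <- sqrt(D / (2 * nu))
  rho <- exp(-nu * dt)
  sd_innov <- R * sqrt(1 - rho^2)    # exact OU transition
  E1 <- as.numeric(stats::filter(stats::rnorm(n, 0, sd_innov), rho,
                                 "recursive", init = stats::rnorm(1, 0, R)))
  E2 <- as.numeric(stats::filter(stats::rnorm(n, 0, sd_innov), rho,
                                 "recursive", init = stats::rnorm(1, 0, R)))
  tt <- (seq_len(n) - 1L) * dt
  keep <- tt >= burn_in
  tt <- tt[keep] - burn_in
  E1 <- E1[keep]; E2 <- E2[keep]
  Z <- sqrt(E1^2 + E2^2)
  phi <- atan2(E2, E1)
  carrier <- reduction$omega0 * tt + phi
  out <- tibble::tibble(time = tt, E1 = E1, E2 = E2, Z = Z, phi = phi,
                        V_E = Z * cos(carrier),
                        V_I = reduction$alpha * Z * cos(carrier - reduction$delta))
  attr(out, "dt") <- dt
  attr(out, "seed") <- seed
  out
}
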