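# Closed-form envelope statistics and mean-first-passage-time theory of
# burst duration.  The stationary envelope is a Rayleigh law with mode
# R = sqrt(D / (2 nu)); mean burst duration is the sum of an up-passage
# (threshold b to ceiling c, reflecting at b) and a down-passage
# (c to b, reflecting at c), each available in closed form through the
# principal-value exponential integral Ei.

#' Stationary envelope law of the transient-synchrony regime
#'
#' @param nu Damping rate (per ms), must be positive.
#' @param D Effective envelope noise strength, must be positive.
#' @return Object of class `envelope_law`: list with `nu`, `D`,
#'   `R = sqrt(D/(2 nu))` (the density mode), `mean_env = sqrt(pi/2) R`,
#'   `sd_env = sqrt((4 - pi)/2) R` and `median_env = sqrt(2 ln 2) R`.
#' @examples
#' law <- envelope_law(nu = 0.0182, D = 0.0706)
#' @export
envelope_law <- function(nu, D) {
  if (!is.numeric(nu) || nu <= 0)
    stop("no stationary envelope law: nu must be positive", call. = FALSE)
  if (!is.numeric(D) || D <= 0)
    stop("D must be positive", call. = FALSE)
  R <- sqrt(D / (2 * nu))
  structure(list(nu = nu, D = D, R = R,
                 mean_env = sqrt(pi / 2) * R,
                 sd_env = sqrt((4 - pi) / 2) * R,
                 median_env = sqrt(2 * log(2)) * R),
            class = "envelope_law")
}

#' @rdname envelope_law
#' @param reduction A `wc_reduction` in the transient-synchrony regime.
#' @export
as_envelope_law <- function(reduction) {
  stopifnot(inherits(reduction, "wc_reduction"))
  envelope_law(reduction$nu, reduction$D)
}

#' Stationary envelope density
#'
#' The Rayleigh density `P(z) = (2 nu / D) z exp(-(nu / D) z^2)`,
#' the stationary solution of the envelope Fokker-Planck equation.
#'
#' @param z Non-negative evaluation points.
#' @param law An [envelope_law()].
#' @return Density values (0 for `z < 0`).
#' @export
stationary_density <- function(z, law) {
  stopifnot(inherits(law, "envelope_law"))
  ifelse(z < 0, 0, (2 * law$nu / law$D) * z * exp(-(law$nu / law$D) * z^2))
}

#' Stationary envelope distribution function
#' @rdname stationary_density
#' @export
stationary_cdf <- function(z, law) {
  stopifnot(inherits(law, "envelope_law"))
  ifelse(z < 0, 0, 1 - exp(-(law$nu / law$D) * z^2))
}

#' Burst threshold pair (b, c) conventions
#'
#' The burst threshold `b` is half the median of the envelope law and `c`
#' is a typical within-burst maximum.  Two conventions are provided:
#' `closed_form` uses the Rayleigh moments, `b = R sqrt(ln(2)/2)` (about
#' `0.59 R`) and `c = R (sqrt(pi/2) + sqrt((4-pi)/2))` (mean plus one SD);
#' `empirical` estimates the same two levels from an observed envelope
#' sample (half its median; its mean plus its SD).
#'
#' @param law An [envelope_law()].
#' @param convention `"closed_form"` or `"empirical"`.
#' @param env Envelope sample (required for `"empirical"`).
#' @return List of class `fpt_spec` with `b`, `c`, `convention`.
#' @export
fpt_thresholds <- function(law, convention = c("closed_form", "empirical"),
                           env = NULL) {
  stopifnot(inherits(law, "envelope_law"))
  convention <- match.arg(convention)
  if (convention == "closed_form") {
    b <- law$R * sqrt(log(2) / 2)
    cc <- law$R * (sqrt(pi / 2) + sqrt((4 - pi) / 2))
  } else {
    if (is.null(env)) stop("empirical convention needs an envelope sample",
                           call. = FALSE)
    b <- stats::median(env) / 2
    cc <- mean(env) + stats::sd(env)
  }
  if (!(b > 0 && b < cc)) stop("thresholds must satisfy 0 < b < c", call. = FALSE)
  structure(list(b = b, c = cc, convention = convention), class = "fpt_spec")
}

check_law_interval <- function(law, b, cc) {
  stopifnot(inherits(law, "envelope_law"))
  if (!(b > 0 && b < cc)) stop("need 0 < b < c", call. = FALSE)
}

#' Mean first passage times of the envelope process
#'
#' Closed forms for the two legs of a burst on the interval `[b, c]`.
#' `mfpt_up()` is the mean time from `z0` up to an absorbing ceiling `c`
#' with a reflecting floor at `b`:
#' `T1(z0) = exp(-nu b^2 / D) / (2 nu) * (Ei(nu c^2 / D) - Ei(nu z0^2 / D))
#'  - log(c / z0) / nu`.
#' `mfpt_down()` is the mean time from `z0` down to an absorbing floor `b`
#' with a reflecting ceiling at `c`:
#' `T2(z0) = exp(-nu c^2 / D) / (2 nu) * (Ei(nu b^2 / D) - Ei(nu z0^2 / D))
#'  + log(z0 / b) / nu`.
#' Note the arguments of the exponential integral are positive.
#'
#' @param law An [envelope_law()].
#' @param z0 Starting envelope value; defaults to `b` for the up-leg and
#'   `c` for the down-leg.
#' @param b,c Floor and ceiling, `0 < b < c`.
#' @return Mean first passage time (ms).
#' @export
mfpt_up <- function(law, b, c, z0 = b) {
  check_law_interval(law, b, c)
  if (!(z0 >= b && z0 <= c)) stop("need b <= z0 <= c", call. = FALSE)
  g <- law$nu / law$D
  exp(-g * b^2) / (2 * law$nu) *
    (pracma::expint_Ei(g * c^2) - pracma::expint_Ei(g * z0^2)) -
    log(c / z0) / law$nu
}

#' @rdname mfpt_up
#' @export
mfpt_down <- function(law, b, c, z0 = c) {
  check_law_interval(law, b, c)
  if (!(z0 >= b && z0 <= c)) stop("need b <= z0 <= c", call. = FALSE)
  g <- law$nu / law$D
  exp(-g * c^2) / (2 * law$nu) *
    (pracma::expint_Ei(g * b^2) - pracma::expint_Ei(g * z0^2)) +
    log(z0 / b) / law$nu
}

#' Theoretical mean burst duration
#'
#' The mean burst duration is the up-passage plus the down-passage,
#' `T = T1(b) + T2(c)`; the logarithmic terms cancel, leaving
#' `T = (1 / (2 nu)) (exp(-(b/R)^2 / 2) - exp(-(c/R)^2 / 2))
#'  (Ei((c/R)^2 / 2) - Ei((b/R)^2 / 2))`,
#' with positive arguments inside `Ei`.  With the closed-form threshold
#' convention both `b/R` and `c/R` are parameter-free constants, so `T` is
#' exactly proportional to `1 / (2 nu)`.
#'
#' A sign variant in which the `Ei` arguments are negated
#' (`form = "negated"`) is retained purely for documentation of the
#' discrepancy: it disagrees with direct Monte-Carlo first-passage
#' simulation of the envelope process (see [mfpt_mc()]), while the default
#' form agrees.
#'
#' @param law An [envelope_law()].
#' @param spec An [fpt_thresholds()] result (defaults to the closed-form
#'   convention).
#' @param form `"passage_sum"` (default, correct) or `"negated"`.
#' @return Mean burst duration (ms).
#' @examples
#' law <- as_envelope_law(quasicycle(wc_point("a")))
#' mean_burst_duration(law)          # about 28 ms
#' @export
mean_burst_duration <- function(law, spec = fpt_thresholds(law),
                                form = c("passage_sum", "negated")) {
  form <- match.arg(form)
  stopifnot(inherits(spec, "fpt_spec"))
  b <- spec$b; cc <- spec$c
  check_law_interval(law, b, cc)
  R <- law$R
  xb <- (b / R)^2 / 2
  xc <- (cc / R)^2 / 2
  s <- if (form == "passage_sum") 1 else -1
  Re((1 / (2 * law$nu)) * (exp(-xb) - exp(-xc)) *
       (pracma::expint_Ei(s * xc) - pracma::expint_Ei(s * xb)))
}

#' Monte-Carlo mean first passage time of the envelope SDE
#'
#' Direct Euler-Maruyama simulation of
#' `dz = (-nu z + D / (2 z)) dt + sqrt(D) dW` on `[b, c]`, with a
#' reflecting boundary (sign-mirroring) at one end and an absorbing
#' boundary at the other, replicated in parallel.  This is the independent
#' oracle for [mfpt_up()] / [mfpt_down()].
#'
#' @param law An [envelope_law()].
#' @param b,c Interval, `0 < b < c`.
#' @param direction `"up"` (start `b`, absorb at `c`, reflect at `b`) or
#'   `"down"` (start `c`, absorb at `b`, reflect at `c`).
#' @param n Number of replicates.
#' @param dt Integration step (ms).
#' @param seed RNG seed.
#' @param max_time Safety cap per replicate (ms); defaults to 50 times the
#'   closed-form prediction.
#' @return List with `mean`, `se` (standard error), `n`, and the vector of
#'   first passage `times`.
#' @export
mfpt_mc <- function(law, b, c, direction = c("up", "down"), n = 10000,
                    dt = 0.01, seed = 1, max_time = NULL) {
  direction <- match.arg(direction)
  check_law_interval(law, b, c)
  set.seed(seed)
  nu <- law$nu; D <- law$D
  theory <- if (direction == "up") mfpt_up(law, b, c) else mfpt_down(law, b, c)
  if (is.null(max_time)) max_time <- 50 * max(theory, dt)
  n_max <- ceiling(max_time / dt)
  sqD <- sqrt(D * dt)

  z <- rep(if (direction == "up") b else c, n)
  alive <- rep(TRUE, n)
  t_hit <- rep(NA_real_, n)
  for (step in seq_len(n_max)) {
    idx <- which(alive)
    if (!length(idx)) break
    zi <- z[idx]
    zi <- zi + (-nu * zi + D / (2 * zi)) * dt + sqD * stats::rnorm(length(idx))
    if (direction == "up") {
      refl <- zi < b
      zi[refl] <- 2 * b - zi[refl]
      hit <- zi >= c
    } else {
      refl <- zi > c
      zi[refl] <- 2 * c - zi[refl]
      hit <- zi <= b
    }
    t_hit[idx[hit]] <- step * dt
    alive[idx[hit]] <- FALSE
    z[idx] <- zi
  }
  times <- t_hit[!is.na(t_hit)]
  if (!length(times)) stop("no replicate reached the boundary within max_time",
                           call. = FALSE)
  list(mean = mean(times), se = stats::sd(times) / sqrt(length(times)),
       n = length(times), times = times)
}

#' Theory table over a parameter sweep
#'
#' Convenience wrapper producing, for each value of a swept parameter, the
#' reduced parameters and the closed-form mean burst duration.
#'
#' @param params Baseline [wc_params()].
#' @param axis Swept parameter name (e.g. `"W_ee"`).
#' @param values Numeric vector of parameter values.
#' @param kind Response-function kind.
#' @return Tibble with `axis`, `nu`, `omega0`, `freq_Hz`, `D`, `R`, `b`,
#'   `c`, `T_theory_ms`.
#' @examples
#' fpt_theory_table(wc_params(), "W_ee", working_point_wee())
#' @export
fpt_theory_table <- function(params, axis = "W_ee",
                             values = working_point_wee(), kind = "logistic") {
  rows <- purrr::map(values, function(v) {
    p <- params
    p[[axis]] <- v
    red <- quasicycle(p, kind = kind)
    if (is.na(red$R)) {
      return(tibble::tibble(!!axis := v, nu = red$nu, omega0 = red$omega0,
                            freq_Hz = red$freq_Hz, D = red$D, R = red$R,
                            b = NA_real_, c = NA_real_,
                            T_theory_ms = NA_real_))
    }
    law <- as_envelope_law(red)
    spec <- fpt_thresholds(law)
    tibble::tibble(!!axis := v, nu = red$nu, omega0 = red$omega0,
                   freq_Hz = red$freq_Hz, D = red$D, R = red$R,
                   b = spec$b, c = spec$c,
                   T_theory_ms = mean_burst_duration(law, spec))
  })
  dplyr::bind_rows(rows)
}

#' Compare an envelope sample with the stationary law
#'
#' @param env Envelope sample.
#' @param law An [envelope_law()].
#' @return A ggplot object: histogram of `env` with the analytic density.
#' @export
plot_envelope_density <- function(env, law) {
  grid <- seq(0, max(env) * 1.05, length.out = 400)
  dens <- tibble::tibble(z = grid, density = stationary_density(grid, law))
  ggplot2::ggplot(tibble::tibble(z = env), ggplot2::aes(.data$z)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey70") +
    ggplot2::geom_line(data = dens, ggplot2::aes(.data$z, .data$density),
                       colour = "red") +
    ggplot2::geom_vline(xintercept = law$R, linetype = 2) +
    ggplot2::labs(x = "envelope", y = "density") +
    ggplot2::theme_minimal()
}
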