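# Analytic-signal and LFP construction tools.  An LFP here is the
# mean-removed, band-passed fluctuation of a population activity (or any
# uniformly sampled trace); envelope and phase come from the FFT analytic
# signal.

# Discrete analytic signal x + i H[x] via the one-sided spectrum.
analytic_fft <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Construct an LFP from a population activity trace
#'
#' Removes the signal mean and applies a band-pass Butterworth filter
#' (default: order 2, 20--100 Hz) in a zero-phase (forward-backward) pass,
#' so that burst timing is not lagged by the filter.
#'
#' @param x Tibble with a uniform `time` column (ms) and the activity in
#'   `value_col`.
#' @param value_col Name of the column to filter (default `"E"`).
#' @param band Two-element band `c(f_lo, f_hi)` in Hz; must lie inside
#'   `(0, Nyquist)`.
#' @param order Butterworth order (default 2).
#' @param scale Multiplier applied to the filtered signal (e.g.
#'   `sqrt(N_E)` to place a microscopic activity on the fluctuation scale
#'   of the linear noise approximation).
#' @return Tibble with columns `time` and `lfp`.
#' @examples
#' tr <- simulate_sam(quasicycle(wc_params()), duration = 2000, seed = 1)
#' lfp <- make_lfp(tr, value_col = "V_E")
#' @export
make_lfp <- function(x, value_col = "E", band = c(20, 100), order = 2,
                     scale = 1) {
  stopifnot(is.data.frame(x), value_col %in% names(x))
  dt <- trace_dt(x)
  fs <- 1000 / dt                       # Hz
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop(sprintf("band (%g, %g) Hz must lie inside (0, Nyquist = %g) Hz",
                 band[1], band[2], fs / 2), call. = FALSE)
  v <- x[[value_col]]
  v <- v - mean(v)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  out <- tibble::tibble(time = x$time,
                        lfp = as.numeric(signal::filtfilt(bf, v)) * scale)
  attr(out, "dt") <- dt
  attr(out, "band") <- band
  out
}

#' Analytic-signal decomposition of a narrowband trace
#'
#' Computes the envelope `sqrt(x^2 + H[x]^2)`, the wrapped phase
#' `atan2(H[x], x)` and the instantaneous frequency (centred difference of
#' the unwrapped phase, smoothed by a moving average) of a zero-mean
#' uniformly sampled trace, using the FFT analytic signal.
#'
#' The identity `envelope * cos(phase) = x` holds to numerical precision;
#' edge-affected samples (the first and last two mean oscillation periods)
#' should be excluded from downstream statistics, which
#' [pair_statistics()] and the burst tools do via `edge_trim`.
#'
#' @param x Tibble with `time` (ms) and the signal in `value_col`.
#' @param value_col Column holding the (zero-mean) signal; default `"lfp"`.
#' @param smooth_ms Width (ms) of the moving average applied to the
#'   instantaneous frequency (default 5 ms).
#' @return Tibble with columns `time`, `signal`, `envelope`, `phase`
#'   (rad, wrapped), `inst_freq` (Hz).
#' @export
analytic_signal <- function(x, value_col = "lfp", smooth_ms = 5) {
  stopifnot(is.data.frame(x), value_col %in% names(x))
  v <- x[[value_col]]
  dt <- trace_dt(x)
  if (length(v) < 8)
    stop("trace too short for analytic-signal decomposition", call. = FALSE)
  v <- v - mean(v)
  a <- analytic_fft(v)
  env <- Mod(a)
  ph <- Arg(a)

  # instantaneous frequency: centred difference of the unwrapped phase
  phu <- unwrap_phase(ph)
  n <- length(phu)
  dphi <- numeric(n)
  dphi[2:(n - 1)] <- (phu[3:n] - phu[1:(n - 2)]) / (2 * dt)
  dphi[1] <- dphi[2]; dphi[n] <- dphi[n - 1]
  w <- max(1L, round(smooth_ms / dt))
  if (w > 1L) {
    kern <- rep(1 / w, w)
    sm <- stats::filter(dphi, kern, sides = 2)
    dphi <- ifelse(is.na(sm), dphi, as.numeric(sm))
  }
  inst_freq <- dphi / (2 * pi) * 1000   # rad/ms -> Hz

  mean_period_samples <- function() {
    f0 <- mean(inst_freq[is.finite(inst_freq)])
    if (!is.finite(f0) || f0 <= 0) return(NA_real_)
    (1000 / f0) / dt
  }
  np <- mean_period_samples()
  if (is.finite(np) && length(v) < 4 * np)
    stop("trace shorter than 4 oscillation periods; edge effects dominate",
         call. = FALSE)

  out <- tibble::tibble(time = x$time, signal = v, envelope = env,
                        phase = ph, inst_freq = inst_freq)
  attr(out, "dt") <- dt
  out
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  jumps <- cumsum(c(0, round(dp / (2 * pi))))
  p - 2 * pi * jumps
}

#' Envelope-ratio and phase-difference statistics of an E-I LFP pair
#'
#' Empirical distributions (and means) of the inhibitory/excitatory
#' envelope ratio and of the E minus I phase difference, from the analytic
#' signals of the two LFPs.  In the linear fluctuation theory these are
#' concentrated around `alpha = sqrt(-A21 / A12)` and the phase lag
#' `delta`; pass a [reduce_lna()] object to attach the closed-form values.
#'
#' @param lfp_E,lfp_I Tibbles on equal time grids with the signals in
#'   `value_col`.
#' @param value_col Signal column name (default `"lfp"`).
#' @param reduction Optional `wc_reduction` with the analytic `alpha`, `delta`.
#' @param edge_trim_periods Mean periods excluded at each end (default 2).
#' @return List with `samples` (tibble: `time`, `ratio`, `phase_diff`),
#'   `mean_ratio`, `mean_phase_diff`, and (when `reduction` is given)
#'   `alpha_theory`, `delta_theory`.
#' @export
pair_statistics <- function(lfp_E, lfp_I, value_col = "lfp", reduction = NULL,
                            edge_trim_periods = 2) {
  stopifnot(nrow(lfp_E) == nrow(lfp_I))
  if (max(abs(lfp_E$time - lfp_I$time)) > 1e-9)
    stop("LFP pair must share one time grid", call. = FALSE)
  dE <- analytic_signal(lfp_E, value_col)
  dI <- analytic_signal(lfp_I, value_col)
  dt <- trace_dt(lfp_E)
  f0 <- mean(dE$inst_freq[is.finite(dE$inst_freq)])
  trim <- ceiling(edge_trim_periods * (1000 / f0) / dt)
  n <- nrow(dE)
  keep <- seq.int(trim + 1L, n - trim)
  ratio <- dI$envelope[keep] / dE$envelope[keep]
  pd <- wrap_angle(dE$phase[keep] - dI$phase[keep])
  out <- list(samples = tibble::tibble(time = dE$time[keep], ratio = ratio,
                                       phase_diff = pd),
              mean_ratio = mean(ratio),
              mean_phase_diff = circular_mean(pd))
  if (!is.null(reduction)) {
    stopifnot(inherits(reduction, "wc_reduction"))
    out$alpha_theory <- reduction$alpha
    out$delta_theory <- reduction$delta
  }
  out
}

circular_mean <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))
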