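# Burst extraction and per-burst statistics.  A burst is an epoch where the
# rhythm envelope stays above a threshold b, subject to a secondary
# criterion that rejects rapid fluctuations: the envelope must also exceed
# the envelope mean on a contiguous stretch of at least two oscillation
# cycles inside the epoch.

#' Burst detection threshold
#'
#' The detection threshold is half the median of the envelope law.  With a
#' known Rayleigh mode `R` this is the closed form
#' `b = R sqrt(ln(2)/2) ~ 0.59 R`; when `R` is unknown (user-supplied
#' data), the empirical fallback is half the median of the observed
#' envelope.
#'
#' @param R Rayleigh mode of the envelope density (optional).
#' @param env Observed envelope values (used when `R` is `NULL`).
#' @return Threshold `b`.
#' @export
burst_threshold <- function(R = NULL, env = NULL) {
  if (!is.null(R)) return(R * sqrt(log(2) / 2))
  if (is.null(env)) stop("supply either R or an envelope sample", call. = FALSE)
  stats::median(env) / 2
}

runs_of <- function(flag) {
  d <- diff(c(FALSE, flag, FALSE))
  cbind(start = which(d == 1), end = which(d == -1) - 1L)
}

#' Extract bursts from an envelope trace
#'
#' Candidate bursts are the maximal intervals on which the envelope
#' exceeds the threshold `b`; a candidate is retained only if it contains
#' a contiguous sub-interval of length at least `min_cycles` oscillation
#' periods (`T0 = 2 pi / omega0`) on which the envelope also exceeds the
#' mean of the envelope process.  Burst boundaries are the threshold
#' crossings, located with sub-sample accuracy by linear interpolation.
#'
#' @param env Tibble with `time` (ms) and the envelope in `value_col`.
#' @param omega0 Angular rhythm frequency (rad/ms), defining the cycle
#'   length used by the secondary criterion.
#' @param value_col Envelope column; default `"Z"`.
#' @param R Rayleigh mode used for the closed-form threshold; when `NULL`
#'   the threshold falls back to half the empirical envelope median.
#' @param threshold Explicit threshold `b` (overrides `R`).
#' @param env_mean Reference level of the secondary criterion; default the
#'   empirical mean of the envelope.
#' @param min_cycles Minimum super-mean stretch, in cycles (default 2).
#' @return Tibble of class `quasiburst_bursts`: `t_start`, `t_end`,
#'   `duration` (ms), `peak_env`; attributes `threshold`, `env_mean`,
#'   `omega0`, `total_time`.
#' @examples
#' red <- quasicycle(wc_point("b"))
#' tr <- simulate_sam(red, duration = 20e3, seed = 2)
#' bursts <- extract_bursts(tr, omega0 = red$omega0, R = red$R)
#' @export
extract_bursts <- function(env, omega0, value_col = "Z", R = NULL,
                           threshold = NULL, env_mean = NULL, min_cycles = 2) {
  stopifnot(is.data.frame(env), value_col %in% names(env), omega0 > 0)
  z <- env[[value_col]]
  if (any(z < 0)) stop("envelope must be non-negative", call. = FALSE)
  tt <- env$time
  dt <- trace_dt(env)
  b <- if (!is.null(threshold)) threshold else burst_threshold(R, z)
  m <- if (!is.null(env_mean)) env_mean else mean(z)
  T0 <- 2 * pi / omega0
  min_len <- min_cycles * T0

  cand <- runs_of(z > b)
  kept <- integer(0)
  if (nrow(cand)) {
    sup <- runs_of(z > m)
    sup_len <- (sup[, "end"] - sup[, "start"] + 1L) * dt
    sup <- sup[sup_len >= min_len, , drop = FALSE]
    if (m <= b) {
      # degenerate ordering: above-threshold implies above-mean, so the
      # criterion reduces to a minimum epoch length
      cand_len <- (cand[, "end"] - cand[, "start"] + 1L) * dt
      kept <- which(cand_len >= min_len)
    } else if (nrow(sup)) {
      # the super-mean stretch must lie inside the above-threshold epoch;
      # locate each stretch's enclosing candidate by binary search
      j <- findInterval(sup[, "start"], cand[, "start"])
      ok <- j >= 1L & sup[, "end"] <= cand[pmax(j, 1L), "end"]
      kept <- sort(unique(j[ok]))
    }
  }
  if (length(kept)) {
    i0 <- cand[kept, "start"]; i1 <- cand[kept, "end"]
    n <- length(z)
    t0 <- ifelse(i0 > 1L,
                 tt[pmax(i0 - 1L, 1L)] +
                   dt * (b - z[pmax(i0 - 1L, 1L)]) /
                   (z[i0] - z[pmax(i0 - 1L, 1L)]),
                 tt[i0])
    t1 <- ifelse(i1 < n,
                 tt[i1] + dt * (z[i1] - b) / (z[i1] - z[pmin(i1 + 1L, n)]),
                 tt[i1])
    peak <- vapply(seq_along(kept),
                   function(q) max(z[i0[q]:i1[q]]), 0)
    out <- tibble::tibble(t_start = t0, t_end = t1, duration = t1 - t0,
                          peak_env = peak)
  } else {
    out <- tibble::tibble(t_start = numeric(0), t_end = numeric(0),
                          duration = numeric(0), peak_env = numeric(0))
  }
  attr(out, "threshold") <- b
  attr(out, "env_mean") <- m
  attr(out, "omega0") <- omega0
  attr(out, "total_time") <- tt[length(tt)] - tt[1]
  class(out) <- c("quasiburst_bursts", class(out))
  out
}

#' Peak frequency of one LFP epoch
#'
#' Frequency of the periodogram maximum of a mean-removed, Hann-windowed,
#' zero-padded LFP epoch, restricted to the analysis band.  Epochs shorter
#' than two cycles of the band's lower edge are reported as `NA`.
#'
#' @param lfp Tibble with `time` and the signal in `value_col`.
#' @param t_start,t_end Epoch limits (ms).
#' @param band Frequency band `c(f_lo, f_hi)` in Hz (default 20--100).
#' @param value_col Signal column (default `"lfp"`).
#' @param pad Zero-padding factor (default 8).
#' @param dt Sampling interval (ms); inferred from `lfp` when omitted.
#' @return Peak frequency in Hz, or `NA` if the epoch is too short.
#' @export
burst_peak_frequency <- function(lfp, t_start, t_end, band = c(20, 100),
                                 value_col = "lfp", pad = 8,
                                 dt = trace_dt(lfp)) {
  n_tot <- nrow(lfp)
  i0 <- max(1L, ceiling((t_start - lfp$time[1]) / dt) + 1L)
  i1 <- min(n_tot, floor((t_end - lfp$time[1]) / dt) + 1L)
  if (i1 < i0) return(NA_real_)
  idx <- i0:i1
  # an epoch must hold at least two periods of the fastest in-band
  # component for any in-band peak estimate to be meaningful
  nmin <- ceiling(2 * (1000 / band[2]) / dt)
  if (length(idx) < max(nmin, 8)) return(NA_real_)
  v <- lfp[[value_col]][idx]
  v <- v - mean(v)
  nseg <- length(v)
  win <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / (nseg - 1)))
  nfft <- 2^ceiling(log2(max(nseg * pad, 4096)))
  spec <- Mod(stats::fft(c(v * win, rep(0, nfft - nseg))))^2
  freqs <- (seq_len(nfft) - 1) / (nfft * dt / 1000)  # Hz
  sel <- freqs >= band[1] & freqs <= band[2]
  freqs[sel][which.max(spec[sel])]
}

#' Attach per-burst peak frequencies to a burst table
#'
#' @param bursts A table from [extract_bursts()].
#' @param lfp The LFP trace the bursts were extracted from (same clock).
#' @param band,value_col,pad Passed to [burst_peak_frequency()].
#' @return `bursts` with a `peak_freq` column (Hz; `NA` for epochs too
#'   short to analyse).
#' @export
add_peak_frequency <- function(bursts, lfp, band = c(20, 100),
                               value_col = "lfp", pad = 8) {
  dt <- trace_dt(lfp)
  pf <- purrr::map2_dbl(bursts$t_start, bursts$t_end,
                        function(a, b) burst_peak_frequency(lfp, a, b, band,
                                                            value_col, pad,
                                                            dt = dt))
  bursts$peak_freq <- pf
  bursts
}

#' Summary statistics of a burst table
#'
#' Mean duration, normalized duration and peak-frequency histograms, the
#' joint duration-frequency histogram, and the peak-frequency-deviation
#' standard deviation: the SD across bursts of
#' `peak_freq - mean(peak_freq)`, computed with the population (`n`)
#' denominator.
#'
#' @param bursts A table from [extract_bursts()], optionally with a
#'   `peak_freq` column from [add_peak_frequency()].
#' @param total_time Total analysed time (ms); defaults to the attribute
#'   recorded at extraction.
#' @param duration_breaks,freq_breaks Histogram breaks (defaults chosen
#'   from the data).
#' @return Object of class `burst_summary`: list with `n_bursts`,
#'   `mean_duration`, `freq_dev_sd`, `mean_peak_freq`, `burst_rate_hz`,
#'   `threshold`, `duration_hist`, `peak_freq_hist`, `joint_hist` (tibbles
#'   of bin midpoints/edges and normalized densities).
#' @export
summarize_bursts <- function(bursts, total_time = attr(bursts, "total_time"),
                             duration_breaks = NULL, freq_breaks = NULL) {
  n <- nrow(bursts)
  out <- list(n_bursts = n,
              threshold = attr(bursts, "threshold"),
              env_mean = attr(bursts, "env_mean"),
              total_time = total_time)
  if (n == 0L) {
    out$mean_duration <- NA_real_
    out$freq_dev_sd <- NA_real_
    return(structure(out, class = "burst_summary"))
  }
  out$mean_duration <- mean(bursts$duration)
  out$burst_rate_hz <- if (!is.null(total_time)) n / (total_time / 1000) else NA_real_
  if (is.null(duration_breaks))
    duration_breaks <- seq(0, max(bursts$duration) * 1.05 + 1e-9, length.out = 31)
  dh <- graphics::hist(bursts$duration, breaks = duration_breaks, plot = FALSE)
  out$duration_hist <- tibble::tibble(mid = dh$mids, density = dh$density)

  pf <- bursts$peak_freq[!is.na(bursts$peak_freq)]
  if (length(pf)) {
    out$mean_peak_freq <- mean(pf)
    out$freq_dev_sd <- sqrt(mean((pf - mean(pf))^2))  # population convention
    if (is.null(freq_breaks))
      freq_breaks <- seq(min(pf) - 1, max(pf) + 1, length.out = 31)
    fh <- graphics::hist(pf, breaks = freq_breaks, plot = FALSE)
    out$peak_freq_hist <- tibble::tibble(mid = fh$mids, density = fh$density)
    ok <- !is.na(bursts$peak_freq)
    jd <- table(cut(bursts$duration[ok], duration_breaks),
                cut(bursts$peak_freq[ok], freq_breaks))
    out$joint_hist <- tibble::as_tibble(as.data.frame(jd / sum(jd),
                                                      stringsAsFactors = FALSE),
                                        .name_repair = ~c("duration_bin",
                                                          "freq_bin", "prob"))
  } else {
    out$mean_peak_freq <- NA_real_
    out$freq_dev_sd <- NA_real_
  }
  structure(out, class = "burst_summary")
}

#' @export
print.burst_summary <- function(x, ...) {
  cat("<burst_summary>\n")
  cat(sprintf("  n bursts: %d  (threshold b = %.4f)\n", x$n_bursts, x$threshold))
  if (x$n_bursts > 0) {
    cat(sprintf("  mean duration: %.2f ms\n", x$mean_duration))
    if (!is.na(x$freq_dev_sd))
      cat(sprintf("  mean peak frequency: %.1f Hz (deviation SD %.2f Hz)\n",
                  x$mean_peak_freq, x$freq_dev_sd))
  }
  invisible(x)
}

#' @rdname summarize_bursts
#' @param x A `burst_summary`.
#' @param ... Unused.
#' @export
glance.burst_summary <- function(x, ...) {
  tibble::tibble(n_bursts = x$n_bursts, mean_duration = x$mean_duration,
                 mean_peak_freq = x$mean_peak_freq %||% NA_real_,
                 freq_dev_sd = x$freq_dev_sd,
                 burst_rate_hz = x$burst_rate_hz %||% NA_real_,
                 threshold = x$threshold)
}

#' Plot burst durations against the envelope trace
#'
#' @param env Envelope tibble (as given to [extract_bursts()]).
#' @param bursts The extracted burst table.
#' @param value_col Envelope column.
#' @return A ggplot object: envelope trace, threshold line and shaded bursts.
#' @export
plot_bursts <- function(env, bursts, value_col = "Z") {
  ggplot2::ggplot(env, ggplot2::aes(x = .data$time, y = .data[[value_col]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_rect(data = as.data.frame(bursts),
                       ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                                    ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, fill = "orange", alpha = 0.3) +
    ggplot2::geom_hline(yintercept = attr(bursts, "threshold"),
                        linetype = 2, colour = "red") +
    ggplot2::labs(x = "time (ms)", y = "envelope") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.burst_summary <- function(object, ...) {
  if (object$n_bursts == 0) stop("no bursts to plot", call. = FALSE)
  ggplot2::ggplot(object$duration_hist, ggplot2::aes(.data$mid, .data$density)) +
    ggplot2::geom_col(width = diff(object$duration_hist$mid[1:2]),
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$mean_duration, colour = "darkgreen") +
    ggplot2::labs(x = "burst duration (ms)", y = "density") +
    ggplot2::theme_minimal()
}
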