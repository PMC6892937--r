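test_that("sub-threshold envelopes contain no bursts", {
  env <- tibble::tibble(time = seq(0, 5000, 0.5), Z = 0.25)
  bursts <- extract_bursts(env, omega0 = 0.5, threshold = 0.5, env_mean = 0.6)
  expect_equal(nrow(bursts), 0)
  s <- summarize_bursts(bursts)
  expect_equal(s$n_bursts, 0)
  expect_true(is.na(s$mean_duration))
})

test_that("designed threshold crossings are recovered exactly", {
  fx <- make_fixture("crossing_envelope", duration = 3000, dt = 0.5,
                     burst_starts = c(400, 1200, 2200),
                     burst_ends = c(700, 1500, 2450))
  b <- attr(fx, "threshold"); m <- attr(fx, "env_mean")
  omega0 <- 0.5                      # T0 ~ 12.6 ms << designed plateaus
  bursts <- extract_bursts(fx, omega0 = omega0, threshold = b, env_mean = m)
  expect_equal(nrow(bursts), 3)
  expect_equal(bursts$t_start, attr(fx, "design_starts"), tolerance = 1e-6)
  expect_equal(bursts$t_end, attr(fx, "design_ends"), tolerance = 1e-6)
  expect_equal(bursts$duration, bursts$t_end - bursts$t_start)

  # a bump whose super-mean plateau is shorter than two cycles is rejected
  short <- make_fixture("crossing_envelope", duration = 1000, dt = 0.5,
                        burst_starts = 400, burst_ends = 418, ramp = 4)
  none <- extract_bursts(short, omega0 = 0.5,
                         threshold = attr(short, "threshold"),
                         env_mean = attr(short, "env_mean"))
  expect_equal(nrow(none), 0)
})

test_that("raising the threshold never increases burst count or durations", {
  red <- point_reductions()$b
  tr <- simulate_sam(red, duration = 60e3, dt = 0.5, seed = 71)
  env <- tibble::tibble(time = tr$time, Z = tr$Z)
  m <- mean(tr$Z)
  b1 <- extract_bursts(env, omega0 = red$omega0, threshold = 0.5 * red$R,
                       env_mean = m)
  b2 <- extract_bursts(env, omega0 = red$omega0, threshold = 0.7 * red$R,
                       env_mean = m)
  # time above threshold is non-increasing in the threshold
  expect_lte(sum(tr$Z > 0.7 * red$R), sum(tr$Z > 0.5 * red$R))
  # every higher-threshold burst is contained in a lower-threshold burst,
  # and is no longer than its container
  for (i in seq_len(nrow(b2))) {
    j <- which(b1$t_start <= b2$t_start[i] + 1e-9 &
                 b1$t_end >= b2$t_end[i] - 1e-9)
    expect_length(j, 1)
    expect_lte(b2$duration[i], b1$duration[j])
  }
  # conservation: total burst time <= time above threshold <= trace length
  dt <- 0.5
  above <- sum(tr$Z > attr(b1, "threshold")) * dt
  expect_lte(sum(b1$duration), above + 2 * dt * nrow(b1))
  expect_lte(above, tr$time[nrow(tr)])
})

test_that("per-burst peak frequency: tones and chirps land where they should", {
  tone <- make_fixture("pure_tone", duration = 500, dt = 0.5, freq = 85)
  lfp <- tibble::tibble(time = tone$time, lfp = tone$value)
  expect_lt(abs(burst_peak_frequency(lfp, 100, 400) - 85), 1)

  chirp <- make_fixture("chirp", duration = 600, dt = 0.5, f0 = 60, f1 = 90)
  lfp2 <- tibble::tibble(time = chirp$time, lfp = chirp$value)
  pk <- burst_peak_frequency(lfp2, 50, 550)
  expect_gt(pk, 60); expect_lt(pk, 90)

  # epoch shorter than two periods of the fastest in-band component -> NA
  expect_true(is.na(burst_peak_frequency(lfp, 100, 115)))
})

test_that("two-point summary statistics use the population convention", {
  bursts <- tibble::tibble(t_start = c(0, 500), t_end = c(100, 620),
                           duration = c(100, 120), peak_env = c(1, 2),
                           peak_freq = c(80, 90))
  attr(bursts, "threshold") <- 0.6
  s <- summarize_bursts(bursts, total_time = 1000)
  expect_equal(s$mean_peak_freq, 85)
  expect_equal(s$freq_dev_sd, 5)        # population (n) denominator
  expect_equal(s$mean_duration, 110)
  expect_equal(s$n_bursts, 2)
})

test_that("SAM burst pipeline returns gamma-band peaks near the carrier", {
  red <- point_reductions()$b
  tr <- simulate_sam(red, duration = 60e3, dt = 0.5, seed = 72)
  env <- tibble::tibble(time = tr$time, Z = tr$Z)
  bursts <- extract_bursts(env, omega0 = red$omega0, R = red$R)
  expect_gt(nrow(bursts), 20)
  lfp <- tibble::tibble(time = tr$time, lfp = tr$V_E)
  bursts <- add_peak_frequency(bursts, lfp)
  pf <- bursts$peak_freq[!is.na(bursts$peak_freq)]
  expect_lt(abs(mean(pf) - red$freq_Hz), 2.5)
  s <- summarize_bursts(bursts)
  expect_true(is.finite(s$freq_dev_sd))
  expect_gt(s$mean_duration, 50)
})
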