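# Configuration-driven experiment runner and synthetic fixtures.

#' Build a reduction directly from the master parameters
#'
#' Users who already know the two master parameters (damping `nu` and
#' envelope noise strength `D`) plus the carrier frequency can construct a
#' reduction object without a biophysical parameter set, e.g. to drive
#' [simulate_sam()] or the burst theory.
#'
#' @param nu Damping rate (per ms), > 0.
#' @param D Envelope noise strength, > 0.
#' @param omega0 Angular carrier frequency (rad/ms), > 0.
#' @param alpha Envelope ratio of the reconstructed inhibitory LFP.
#' @param delta Phase lag (rad) of the reconstructed inhibitory LFP.
#' @return A `wc_reduction` object (without attached coefficients).
#' @export
reduction_from_master <- function(nu, D, omega0, alpha = 1, delta = pi / 2) {
  stopifnot(nu > 0, D > 0, omega0 > 0)
  structure(list(nu = nu, omega0 = omega0,
                 freq_Hz = omega0 / (2 * pi) * 1000, D = D,
                 R = sqrt(D / (2 * nu)), alpha = alpha,
                 delta = wrap_angle(delta),
                 regime = "transient_synchrony", coeffs = NULL),
            class = "wc_reduction")
}

experiment_schema <- c("params", "working_point", "level", "duration", "dt",
                       "dt_out", "seed", "band", "burst_convention",
                       "min_cycles", "burn_in", "output_dir")

#' Run a configuration-driven experiment
#'
#' Ties the pipeline together: reduce the parameter set, simulate at the
#' requested level (`"gillespie"`, `"rate_sde"`, `"lna"` or `"sam"`),
#' construct the LFP and envelope, extract bursts with the two-cycle
#' criterion, attach per-burst peak frequencies and summarize.  Reruns
#' with the same config (including `seed`) are identical.
#'
#' @param config Named list, or path to a YAML/JSON file containing one.
#'   Recognized keys: `params` (list of [wc_params()] overrides, or a path
#'   for [read_params()]), `working_point` (`"a"`--`"d"`, applied before
#'   overrides), `level`, `duration` (ms), `dt`, `dt_out`, `seed`, `band`
#'   (Hz pair), `burst_convention` (`"closed_form"` or `"empirical"`),
#'   `min_cycles`, `burn_in`, `output_dir`.  Unknown keys are an error,
#'   reported together before any computation.
#' @return List of class `quasiburst_experiment`: `reduction`, `trace`,
#'   `lfp`, `envelope`, `bursts`, `summary`, `manifest`.
#' @examples
#' ex <- run_experiment(list(working_point = "b", level = "sam",
#'                           duration = 20e3, seed = 1))
#' glance(ex$summary)
#' @export
run_experiment <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      yaml = ,
      yml  = yaml::read_yaml(config),
      json = jsonlite::read_json(config, simplifyVector = TRUE),
      stop("unsupported config format: .", ext, call. = FALSE))
  }
  stopifnot(is.list(config))
  problems <- character(0)
  bad <- setdiff(names(config), experiment_schema)
  if (length(bad))
    problems <- c(problems, paste0("unknown config key(s): ",
                                   paste(bad, collapse = ", ")))
  level <- config$level %||% "sam"
  if (!level %in% c("gillespie", "rate_sde", "lna", "sam"))
    problems <- c(problems, paste0("unknown level: ", level))
  duration <- config$duration %||% 10e3
  if (!is.numeric(duration) || duration <= 0)
    problems <- c(problems, "duration must be positive")
  conv <- config$burst_convention %||% "closed_form"
  if (!conv %in% c("closed_form", "empirical"))
    problems <- c(problems, paste0("unknown burst_convention: ", conv))
  if (length(problems))
    stop(paste(problems, collapse = "; "), call. = FALSE)

  seed <- config$seed %||% 1L
  band <- config$band %||% c(20, 100)
  min_cycles <- config$min_cycles %||% 2

  params <- if (!is.null(config$working_point)) wc_point(config$working_point)
            else wc_params()
  if (!is.null(config$params)) {
    if (is.character(config$params)) {
      params <- read_params(config$params)
    } else {
      base <- unclass(params)
      base[names(config$params)] <- config$params
      params <- do.call(wc_params, base)
    }
  }

  red <- quasicycle(params)

  if (level == "sam") {
    dt <- config$dt %||% 0.1
    trace <- simulate_sam(red, duration, dt = dt, seed = seed,
                          burn_in = config$burn_in %||% 0)
    lfp <- tibble::tibble(time = trace$time, lfp = trace$V_E)
    envelope <- tibble::tibble(time = trace$time, Z = trace$Z)
    bursts <- extract_bursts(envelope, omega0 = red$omega0, R = red$R,
                             min_cycles = min_cycles)
  } else {
    if (level == "gillespie") {
      dt <- config$dt_out %||% 0.5
      trace <- simulate_gillespie(params, duration, seed = seed, dt_out = dt,
                                  burn_in = config$burn_in %||% 500)
      lfp <- make_lfp(trace, "E", band = band, scale = sqrt(params$N_E))
    } else if (level == "rate_sde") {
      trace <- simulate_rate_sde(params, duration, dt = config$dt %||% 0.01,
                                 dt_out = config$dt_out %||% 0.5, seed = seed,
                                 burn_in = config$burn_in %||% 500)
      lfp <- make_lfp(trace, "E", band = band, scale = sqrt(params$N_E))
    } else {
      trace <- simulate_lna(lna_coefficients(params), duration,
                            dt = config$dt %||% 0.5, seed = seed,
                            burn_in = config$burn_in %||% 500)
      lfp <- make_lfp(trace, "V_E", band = band)
    }
    dec <- analytic_signal(lfp)
    envelope <- tibble::tibble(time = dec$time, Z = dec$envelope)
    R_use <- if (conv == "closed_form" && !is.na(red$R)) red$R else NULL
    bursts <- extract_bursts(envelope, omega0 = red$omega0, R = R_use,
                             min_cycles = min_cycles)
  }

  bursts <- add_peak_frequency(bursts, lfp, band = band)
  summ <- summarize_bursts(bursts)

  manifest <- list(
    package = "quasiburst",
    version = as.character(utils::packageVersion("quasiburst")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    level = level, seed = seed, duration = duration,
    config = config,
    config_hash = rlang::hash(config),
    params = unclass(params),
    reduction = as.list(tidy(red)))

  out <- list(reduction = red, trace = trace, lfp = lfp, envelope = envelope,
              bursts = bursts, summary = summ, manifest = manifest)
  class(out) <- "quasiburst_experiment"

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trace, file.path(config$output_dir, "trace.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(bursts),
                     file.path(config$output_dir, "bursts.csv"),
                     row.names = FALSE)
    utils::write.csv(tidy(red), file.path(config$output_dir, "reduction.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  out
}

#' @export
print.quasiburst_experiment <- function(x, ...) {
  cat("<quasiburst_experiment> level:", x$manifest$level,
      " seed:", x$manifest$seed, "\n")
  print(x$summary)
  invisible(x)
}

#' Deterministic synthetic test traces
#'
#' Generates traces with analytically known properties, used by the test
#' suites and available for user diagnostics:
#' \describe{
#'   \item{`pure_tone`}{`cos(2 pi f t)`, unit amplitude.}
#'   \item{`chirp`}{linear frequency sweep `f0 -> f1`.}
#'   \item{`crossing_envelope`}{piecewise-linear envelope crossing a
#'     threshold `b` exactly at prescribed times, with super-mean plateaus
#'     (designed burst boundaries are returned as attributes).}
#'   \item{`ou_pair`}{envelope/phase of two independent OU processes with
#'     given `nu`, `D` (wraps [simulate_sam()]).}
#' }
#'
#' @param kind Fixture kind (see above).
#' @param duration Duration (ms).
#' @param dt Sampling step (ms).
#' @param freq,f0,f1 Frequencies in Hz (tone; chirp ends).
#' @param b,env_mean,peak,baseline,ramp Crossing-envelope geometry:
#'   threshold, secondary-criterion level, plateau height, resting level,
#'   ramp half-width (ms).
#' @param burst_starts,burst_ends Designed threshold-crossing times (ms).
#' @param nu,D,omega0 OU-pair master parameters.
#' @param seed RNG seed (ou_pair only).
#' @return A tibble; for `crossing_envelope` with attributes
#'   `design_starts`, `design_ends`, `threshold`, `env_mean`.
#' @export
make_fixture <- function(kind = c("pure_tone", "chirp", "crossing_envelope",
                                  "ou_pair"),
                         duration = 1000, dt = 0.1, freq = 85,
                         f0 = 60, f1 = 90,
                         b = 1, env_mean = 1.5, peak = 2.2, baseline = 0.3,
                         ramp = 5,
                         burst_starts = c(200, 600), burst_ends = c(320, 760),
                         nu = 0.0182, D = 0.0706, omega0 = 0.5,
                         seed = 1) {
  kind <- match.arg(kind)
  tt <- seq(0, duration, by = dt)
  switch(kind,
    pure_tone = tibble::tibble(time = tt,
                               value = cos(2 * pi * freq * tt / 1000)),
    chirp = {
      f_inst <- f0 + (f1 - f0) * tt / duration
      phase <- 2 * pi * cumsum(f_inst) * dt / 1000
      tibble::tibble(time = tt, value = cos(phase))
    },
    crossing_envelope = {
      stopifnot(length(burst_starts) == length(burst_ends),
                all(burst_ends > burst_starts),
                baseline < b, b < env_mean, env_mean < peak)
      pts_t <- 0; pts_v <- baseline
      for (i in seq_along(burst_starts)) {
        s <- burst_starts[i]; e <- burst_ends[i]
        pts_t <- c(pts_t, s - ramp, s, s + ramp, e - ramp, e, e + ramp)
        pts_v <- c(pts_v, baseline, b, peak, peak, b, baseline)
      }
      pts_t <- c(pts_t, duration); pts_v <- c(pts_v, baseline)
      z <- stats::approx(pts_t, pts_v, xout = tt, rule = 2)$y
      out <- tibble::tibble(time = tt, Z = z)
      attr(out, "design_starts") <- burst_starts
      attr(out, "design_ends") <- burst_ends
      attr(out, "threshold") <- b
      attr(out, "env_mean") <- env_mean
      out
    },
    ou_pair = simulate_sam(reduction_from_master(nu, D, omega0),
                           duration, dt = dt, seed = seed))
}
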