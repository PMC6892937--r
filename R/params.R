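#' Biophysical parameters of the stochastic E-I network
#'
#' Constructs and validates the twelve parameters of a fully connected
#' excitatory-inhibitory network of two-state (quiescent/active) neurons.
#' Each neuron decays from active to quiescent at a constant rate
#' (`alpha_E`, `alpha_I`, per ms) and activates at rate `beta * f(s)`,
#' where `f` is the input-output response function and `s` the total
#' synaptic input.  Defaults are the canonical gamma-band working point of
#' the model (the "point b" set, recurrent excitation `W_ee = 27.4`).
#'
#' @param alpha_E,alpha_I Decay rates of excitatory / inhibitory cells (per ms).
#' @param beta_E,beta_I Maximal activation rates (per ms).
#' @param h_E,h_I External inputs (dimensionless).
#' @param W_ee,W_ii,W_ei,W_ie Non-negative synaptic strengths: recurrent
#'   excitation, recurrent inhibition, inhibitory-to-excitatory and
#'   excitatory-to-inhibitory coupling.
#' @param N_E,N_I Positive integer population sizes.
#'
#' @return An object of class `wc_params` (a named list).
#' @examples
#' p <- wc_params()                 # canonical parameter set
#' p2 <- wc_params(W_ee = 20.4)     # far-from-transition variant
#' @seealso [wc_point()] for the four named working points,
#'   [read_params()] / [write_params()] for config files.
#' @export
wc_params <- function(alpha_E = 0.1, alpha_I = 0.2,
                      beta_E = 1, beta_I = 2,
                      h_E = -3.8, h_I = -8,
                      W_ee = 27.4, W_ii = 1.3, W_ei = 26.3, W_ie = 32,
                      N_E = 800, N_I = 200) {
  p <- list(alpha_E = alpha_E, alpha_I = alpha_I,
            beta_E = beta_E, beta_I = beta_I,
            h_E = h_E, h_I = h_I,
            W_ee = W_ee, W_ii = W_ii, W_ei = W_ei, W_ie = W_ie,
            N_E = N_E, N_I = N_I)
  validate_wc_params(p)
  structure(p, class = "wc_params")
}

validate_wc_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("parameter `", nm, "` must be a single finite number",
                             call. = FALSE)
  }
  for (nm in c("alpha_E", "alpha_I")) {
    if (p[[nm]] <= 0) stop("decay rate `", nm, "` must be positive", call. = FALSE)
  }
  for (nm in c("beta_E", "beta_I")) {
    if (p[[nm]] < 0) stop("rate `", nm, "` must be non-negative", call. = FALSE)
  }
  for (nm in c("W_ee", "W_ii", "W_ei", "W_ie")) {
    if (p[[nm]] < 0) stop("synaptic strength `", nm, "` must be non-negative",
                          call. = FALSE)
  }
  for (nm in c("N_E", "N_I")) {
    if (p[[nm]] < 1 || p[[nm]] != round(p[[nm]]))
      stop("population size `", nm, "` must be a positive integer", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.wc_params <- function(x, ...) {
  cat("<wc_params> stochastic E-I network parameters\n")
  cat(sprintf("  decay      alpha_E = %g, alpha_I = %g (per ms)\n", x$alpha_E, x$alpha_I))
  cat(sprintf("  activation beta_E  = %g, beta_I  = %g (per ms)\n", x$beta_E, x$beta_I))
  cat(sprintf("  input      h_E = %g, h_I = %g\n", x$h_E, x$h_I))
  cat(sprintf("  coupling   W_ee = %g, W_ii = %g, W_ei = %g, W_ie = %g\n",
              x$W_ee, x$W_ii, x$W_ei, x$W_ie))
  cat(sprintf("  size       N_E = %d, N_I = %d\n", as.integer(x$N_E), as.integer(x$N_I)))
  invisible(x)
}

#' Named working points of the transient-synchrony regime
#'
#' Four presets `"a"`--`"d"` lying on a horizontal line in the
#' (`W_ee`, `W_ii`) plane at `W_ee = 20.4, 27.4, 28.4, 29.4`, increasingly
#' close to the Hopf transition between transient and high synchrony.  All
#' other parameters are the [wc_params()] defaults.
#'
#' @param point One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @return A `wc_params` object.
#' @examples
#' glance(quasicycle(wc_point("d")))
#' @export
wc_point <- function(point = c("a", "b", "c", "d")) {
  point <- match.arg(point)
  wee <- c(a = 20.4, b = 27.4, c = 28.4, d = 29.4)[[point]]
  wc_params(W_ee = wee)
}

#' The four working-point recurrent-excitation values
#' @return Named numeric vector of `W_ee` values for points a--d.
#' @export
working_point_wee <- function() c(a = 20.4, b = 27.4, c = 28.4, d = 29.4)

#' Read / write network parameters as flat config files
#'
#' Parameter sets are stored as flat key:value mappings in YAML or JSON
#' (chosen from the file extension).  Keys missing from the file fall back
#' to the [wc_params()] defaults; unknown keys are an error.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param params A `wc_params` object (for writing).
#' @return `read_params()` returns a `wc_params`; `write_params()` returns
#'   `path` invisibly.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, call. = FALSE))
  known <- names(formals(wc_params))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(wc_params, raw)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "wc_params"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(params)
  switch(ext,
    yaml = ,
    yml  = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported config format: .", ext, call. = FALSE))
  invisible(path)
}
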