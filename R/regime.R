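#' Map dynamical regimes over a two-parameter plane
#'
#' Evaluates the envelope-phase reduction on a grid in any two of the
#' connectivity / input parameters (`W_ee`, `W_ii`, `W_ei`, `W_ie`, `h_E`,
#' `h_I`), holding all other parameters fixed, and labels each cell with
#' its dynamical regime.  The `nu = 0` contour separates transient from
#' high synchrony (the Hopf transition); the boundary where the
#' eigenvalues become real separates the oscillatory regimes from the
#' non-oscillatory ones.
#'
#' Cells whose fixed-point solve fails are marked `regime = "invalid"`
#' rather than aborting the map.
#'
#' @param params Baseline [wc_params()].
#' @param axis1,axis2 Parameter names (distinct, from the set above).
#' @param grid1,grid2 Numeric vectors of axis values.
#' @param kind Response-function kind.
#' @return Tibble with columns `axis1` name, `axis2` name, `regime`, `nu`,
#'   `omega0_Hz`, `D`, `R`.
#' @examples
#' m <- regime_map(wc_params(), "W_ee", c(20.4, 29.4), "W_ii", c(1.3, 2))
#' @export
regime_map <- function(params, axis1, grid1, axis2, grid2, kind = "logistic") {
  axes <- c("W_ee", "W_ii", "W_ei", "W_ie", "h_E", "h_I")
  if (!axis1 %in% axes || !axis2 %in% axes || axis1 == axis2)
    stop("axis1 and axis2 must be two distinct parameters among: ",
         paste(axes, collapse = ", "), call. = FALSE)
  cells <- tidyr::expand_grid(a1 = grid1, a2 = grid2)
  rows <- purrr::pmap(cells, function(a1, a2) {
    p <- params
    p[[axis1]] <- a1
    p[[axis2]] <- a2
    red <- tryCatch(quasicycle(p, kind = kind), error = function(e) NULL)
    if (is.null(red)) {
      return(tibble::tibble(a1 = a1, a2 = a2, regime = "invalid",
                            nu = NA_real_, omega0_Hz = NA_real_,
                            D = NA_real_, R = NA_real_))
    }
    tibble::tibble(a1 = a1, a2 = a2, regime = red$regime, nu = red$nu,
                   omega0_Hz = red$freq_Hz, D = red$D, R = red$R)
  })
  out <- dplyr::bind_rows(rows)
  names(out)[1:2] <- c(axis1, axis2)
  class(out) <- c("quasiburst_regime_map", class(out))
  out
}

#' Locate the Hopf transition along one parameter
#'
#' Bisects the damping rate `nu` (as a function of a single swept
#' parameter) to the point where it changes sign, i.e. the transition
#' between the transient-synchrony and high-synchrony regimes.
#'
#' @param params Baseline [wc_params()].
#' @param axis Name of the swept parameter.
#' @param interval Length-2 numeric bracket; `nu` must change sign across it.
#' @param tol Bisection tolerance on the parameter.
#' @param kind Response-function kind.
#' @return The critical parameter value where `nu = 0`.
#' @export
find_transition <- function(params, axis, interval, tol = 1e-6,
                            kind = "logistic") {
  nu_of <- function(v) {
    p <- params
    p[[axis]] <- v
    quasicycle(p, kind = kind)$nu
  }
  lo <- min(interval); hi <- max(interval)
  f_lo <- nu_of(lo); f_hi <- nu_of(hi)
  if (sign(f_lo) == sign(f_hi))
    stop("nu does not change sign over the bracket", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- nu_of(mid)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else hi <- mid
  }
  (lo + hi) / 2
}

#' Plot a regime map
#'
#' @param object A tibble from [regime_map()].
#' @param fill One of `"regime"`, `"nu"`, `"R"`, `"omega0_Hz"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quasiburst_regime_map <- function(object, fill = "regime", ...) {
  plot_regime_map(object, fill = fill)
}

#' @rdname autoplot.quasiburst_regime_map
#' @param map Tibble from [regime_map()].
#' @export
plot_regime_map <- function(map, fill = "regime") {
  ax <- names(map)[1:2]
  ggplot2::ggplot(map, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                    fill = .data[[fill]])) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = ax[1], y = ax[2]) +
    ggplot2::theme_minimal()
}
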