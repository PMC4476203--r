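#' Poiseuille resistance of a cylindrical vessel
#'
#' Hydraulic resistance of fully developed laminar flow in a straight rigid
#' pipe: `R = 128 * mu * L / (pi * D^4)`. This is the constitutive law for
#' every element of the network; note the fourth-power sensitivity to the
#' diameter, which is what makes stenosis so effective at raising upstream
#' pressure.
#'
#' @param length Vessel length in metres. Vectorised.
#' @param diameter Equivalent lumen diameter in metres. Vectorised.
#' @param viscosity Dynamic viscosity of blood in Pa s (default 0.003, i.e.
#'   3 cPoise).
#' @return Resistance in Pa s / m^3.
#' @examples
#' poiseuille_resistance(0.1, 0.01)          # ~1.22e6 Pa s/m^3
#' poiseuille_resistance(0.1, 0.005) / poiseuille_resistance(0.1, 0.01) # 16
#' @export
poiseuille_resistance <- function(length, diameter, viscosity = 0.003) {
  if (any(!is.finite(length)) || any(length <= 0)) {
    abort("`length` must be finite and > 0.")
  }
  if (any(!is.finite(diameter)) || any(diameter <= 0)) {
    abort("`diameter` must be finite and > 0.")
  }
  if (any(!is.finite(viscosity)) || any(viscosity <= 0)) {
    abort("`viscosity` must be finite and > 0.")
  }
  128 * viscosity * length / (pi * diameter^4)
}

#' Equivalent resistance of elements in series
#'
#' @param values Numeric vector of resistances (Pa s/m^3), all > 0.
#' @return The arithmetic sum.
#' @export
series_resistance <- function(values) {
  check_resistances(values)
  sum(values)
}

#' Equivalent resistance of elements in parallel
#'
#' @inheritParams series_resistance
#' @return `1 / sum(1 / values)`.
#' @export
parallel_resistance <- function(values) {
  check_resistances(values)
  1 / sum(1 / values)
}

check_resistances <- function(values) {
  if (length(values) == 0) abort("resistance list must be non-empty.")
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort("resistances must be finite and > 0.")
  }
  invisible(values)
}

#' Reynolds number of pipe flow
#'
#' `Re = 4 * rho * |Q| / (pi * mu * D)` for volumetric flow rate Q in a pipe
#' of diameter D. Values well below ~2000 indicate laminar flow, the regime in
#' which the Poiseuille resistance model is valid.
#'
#' @param flow Volumetric flow rate in m^3/s (sign ignored). Vectorised.
#' @param diameter Pipe diameter in metres.
#' @param density Fluid density in kg/m^3 (default 1060, whole blood).
#' @param viscosity Dynamic viscosity in Pa s (default 0.003).
#' @return Dimensionless Reynolds number.
#' @seealso [reynolds_numbers()] for a per-vessel table from a solved network.
#' @export
reynolds_number <- function(flow, diameter, density = 1060, viscosity = 0.003) {
  if (any(!is.finite(diameter)) || any(diameter <= 0)) {
    abort("`diameter` must be finite and > 0.")
  }
  if (any(!is.finite(density)) || any(density <= 0)) {
    abort("`density` must be finite and > 0.")
  }
  if (any(!is.finite(viscosity)) || any(viscosity <= 0)) {
    abort("`viscosity` must be finite and > 0.")
  }
  4 * density * abs(flow) / (pi * viscosity * diameter)
}
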