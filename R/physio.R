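#' Unit conversion between mmHg and barye
#'
#' All internal pressures are in CGS units (barye = dyne/cm^2); mmHg
#' appears only at user interfaces. The fixed conversion factor is
#' 1 mmHg = 1333.22 dyne/cm^2.
#'
#' @param p numeric vector of pressures.
#' @return Converted pressures.
#' @export
mmHg_to_barye <- function(p) p * 1333.22

#' @rdname mmHg_to_barye
#' @export
barye_to_mmHg <- function(p) p / 1333.22

#' Blood fluid properties
#'
#' Newtonian blood model constants in CGS units. Defaults are the
#' values commonly used for cerebral CFD: density 1.06 g/cm^3 and
#' dynamic viscosity 0.04 Poise.
#'
#' @param density blood density in g/cm^3; must be > 0.
#' @param viscosity dynamic viscosity in Poise (dyne s/cm^2); must be > 0.
#' @return An object of class `fluid_properties`.
#' @examples
#' props <- fluid_properties()
#' props$viscosity
#' @export
fluid_properties <- function(density = 1.06, viscosity = 0.04) {
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("`density` must be a single positive number (g/cm^3)", call. = FALSE)
  }
  if (!is.numeric(viscosity) || length(viscosity) != 1L ||
      !is.finite(viscosity) || viscosity <= 0) {
    stop("`viscosity` must be a single positive number (Poise)", call. = FALSE)
  }
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("Fluid properties: density", x$density, "g/cm^3, viscosity",
      x$viscosity, "Poise\n")
  invisible(x)
}

#' Poiseuille wall shear stress
#'
#' Closed-form wall shear stress of fully developed laminar flow in a
#' straight circular tube, tau = 4 mu Q / (pi R^3). Used as the
#' physical anchor for synthetic parent-artery shear levels.
#'
#' @param props a [fluid_properties()] object.
#' @param flow volumetric flow rate in cm^3/s.
#' @param radius tube radius in cm; must be > 0.
#' @return Wall shear stress in dyne/cm^2.
#' @examples
#' poiseuille_wss(fluid_properties(), flow = 4, radius = 0.2)
#' @export
poiseuille_wss <- function(props, flow, radius) {
  stopifnot(inherits(props, "fluid_properties"))
  if (!is.numeric(radius) || any(!is.finite(radius)) || any(radius <= 0)) {
    stop("`radius` must be positive (cm)", call. = FALSE)
  }
  if (!is.numeric(flow) || any(!is.finite(flow))) {
    stop("`flow` must be finite (cm^3/s)", call. = FALSE)
  }
  4 * props$viscosity * flow / (pi * radius^3)
}
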