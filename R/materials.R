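#' Dielectric material
#'
#' A material characterised by its relative permittivity and its conductivity.
#' Materials are the inputs to the complex-permittivity model
#' \eqn{\varepsilon^*(f) = \varepsilon - j\sigma/(2\pi f)} that drives both the
#' Clausius-Mossotti factor and the capacitance formulas.
#'
#' @param epsilon_r relative permittivity (dimensionless, \eqn{\ge 1} for
#'   ordinary media; values below 1 raise a warning but are accepted).
#' @param sigma conductivity in S/m (\eqn{\ge 0}).
#' @param name optional label used in printing.
#' @return An object of class `dielectric_material`.
#' @examples
#' water <- dielectric_material(80, 1e-4, name = "DI water")
#' complex_permittivity(water, 1e6)
#' @export
dielectric_material <- function(epsilon_r, sigma = 0, name = NULL) {
  check_number(epsilon_r, "epsilon_r", min = 0, strict_min = TRUE)
  if (epsilon_r < 1)
    warning("epsilon_r < 1 is unphysical for ordinary media", call. = FALSE)
  check_number(sigma, "sigma", min = 0)
  structure(list(epsilon_r = epsilon_r, sigma = sigma, name = name),
            class = "dielectric_material")
}

#' @export
print.dielectric_material <- function(x, ...) {
  cat("Dielectric material", if (!is.null(x$name)) paste0("'", x$name, "'"),
      "\n  epsilon_r =", x$epsilon_r,
      "\n  sigma     =", si_format(x$sigma, "S/m"), "\n")
  invisible(x)
}

#' Complex permittivity of a material
#'
#' \eqn{\varepsilon^*(f) = \varepsilon_r\varepsilon_0 - j\,\sigma/(2\pi f)}.
#' A lossless material (\eqn{\sigma = 0}) is purely real at any frequency; the
#' imaginary part vanishes as \eqn{f \to \infty}.
#'
#' @param material a [dielectric_material()].
#' @param f frequency in Hz (may be a vector; all entries > 0).
#' @return complex permittivity in F/m (same length as `f`).
#' @export
complex_permittivity <- function(material, f) {
  stopifnot(inherits(material, "dielectric_material"))
  if (any(!is.finite(f)) || any(f <= 0))
    stop_domain("f must be positive and finite")
  complex(real = material$epsilon_r * EPS0,
          imaginary = -material$sigma / (2 * pi * f))
}

#' Spherical particle
#'
#' A homogeneous dielectric sphere, the particle model underlying the
#' Clausius-Mossotti factor and the DEP force law.
#'
#' @param radius particle radius in m (> 0).
#' @param material a [dielectric_material()] giving the particle's bulk
#'   (or effective) permittivity and conductivity.
#' @param name optional label.
#' @return An object of class `spherical_particle`.
#' @export
spherical_particle <- function(radius, material, name = NULL) {
  check_number(radius, "radius", min = 0, strict_min = TRUE)
  stopifnot(inherits(material, "dielectric_material"))
  structure(list(radius = radius, material = material, name = name),
            class = "spherical_particle")
}

#' @export
print.spherical_particle <- function(x, ...) {
  cat("Spherical particle", if (!is.null(x$name)) paste0("'", x$name, "'"),
      "\n  radius =", si_format(x$radius, "m"),
      "\n  epsilon_r =", x$material$epsilon_r,
      ", sigma =", si_format(x$material$sigma, "S/m"), "\n")
  invisible(x)
}

#' Particle suspension
#'
#' A particle in a carrier medium, with the hydrodynamic properties needed by
#' the trajectory simulator (Stokes drag and the buoyant centrifugal force).
#'
#' @param particle a [spherical_particle()].
#' @param medium a [dielectric_material()] for the carrier fluid.
#' @param viscosity dynamic viscosity in Pa s (default 1e-3, water at 20 C).
#' @param density_particle particle density in kg/m^3 (default 1050,
#'   polystyrene).
#' @param density_medium medium density in kg/m^3 (default 1000, water).
#' @return An object of class `suspension`.
#' @export
suspension <- function(particle, medium, viscosity = 1.0e-3,
                       density_particle = 1050, density_medium = 1000) {
  stopifnot(inherits(particle, "spherical_particle"),
            inherits(medium, "dielectric_material"))
  check_number(viscosity, "viscosity", min = 0, strict_min = TRUE)
  check_number(density_particle, "density_particle", min = 0, strict_min = TRUE)
  check_number(density_medium, "density_medium", min = 0, strict_min = TRUE)
  structure(list(particle = particle, medium = medium, viscosity = viscosity,
                 density_particle = density_particle,
                 density_medium = density_medium),
            class = "suspension")
}

#' @export
print.suspension <- function(x, ...) {
  cat("Suspension:\n")
  cat("  particle: r =", si_format(x$particle$radius, "m"),
      " epsilon_r =", x$particle$material$epsilon_r,
      " sigma =", si_format(x$particle$material$sigma, "S/m"), "\n")
  cat("  medium:   epsilon_r =", x$medium$epsilon_r,
      " sigma =", si_format(x$medium$sigma, "S/m"), "\n")
  cat("  viscosity =", si_format(x$viscosity, "Pa s"),
      " densities =", x$density_particle, "/", x$density_medium, "kg/m^3\n")
  invisible(x)
}
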