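# Clausius-Mossotti factor, its spectrum and crossover, and the DEP force
# law for a homogeneous dielectric sphere.

#' Clausius-Mossotti factor
#'
#' \eqn{K(f) = (\varepsilon_p^* - \varepsilon_m^*) /
#' (\varepsilon_p^* + 2\varepsilon_m^*)} with the complex permittivities
#' \eqn{\varepsilon^*(f) = \varepsilon - j\sigma/(2\pi f)}.  The real part
#' sets the sign and strength of the DEP force: positive values pull the
#' particle toward field maxima (electrode edges), negative values push it
#' away.  For a homogeneous sphere \eqn{Re[K]} is bounded in \[-0.5, 1\].
#'
#' @param particle a [spherical_particle()].
#' @param medium a [dielectric_material()].
#' @param f frequency in Hz (scalar or vector, > 0).
#' @return complex K(f), same length as `f`.
#' @examples
#' ps <- spherical_particle(2.5e-6, dielectric_material(2.55, 0))
#' water <- dielectric_material(80, 0)
#' Re(clausius_mossotti(ps, water, 1e8))  # -> -0.476, negative DEP
#' @export
clausius_mossotti <- function(particle, medium, f) {
  stopifnot(inherits(particle, "spherical_particle"),
            inherits(medium, "dielectric_material"))
  ep <- complex_permittivity(particle$material, f)
  em <- complex_permittivity(medium, f)
  den <- ep + 2 * em
  if (any(Mod(den) == 0))
    stop_domain("singular Clausius-Mossotti denominator (eps_p* + 2 eps_m* = 0)")
  (ep - em) / den
}

#' Clausius-Mossotti spectrum
#'
#' [clausius_mossotti()] evaluated on a log-spaced frequency grid; DEP spectra
#' span decades, so log spacing is the natural sampling.
#'
#' @param particle a [spherical_particle()].
#' @param medium a [dielectric_material()].
#' @param f_min,f_max frequency range in Hz (0 < f_min < f_max).
#' @param n_points number of grid points (>= 2).
#' @return An object of class `cm_spectrum` with `frequencies`, `k_complex`,
#'   `re_k`.
#' @export
cm_spectrum <- function(particle, medium, f_min = 1e3, f_max = 1e9,
                        n_points = 200) {
  check_number(f_min, "f_min", min = 0, strict_min = TRUE)
  check_number(f_max, "f_max", min = f_min, strict_min = TRUE)
  check_count(n_points, "n_points", min = 2L)
  freqs <- exp(seq(log(f_min), log(f_max), length.out = n_points))
  k <- clausius_mossotti(particle, medium, freqs)
  structure(list(frequencies = freqs, k_complex = k, re_k = Re(k),
                 particle = particle, medium = medium),
            class = "cm_spectrum")
}

#' @export
print.cm_spectrum <- function(x, ...) {
  cat("Clausius-Mossotti spectrum:", length(x$frequencies), "points,",
      si_format(min(x$frequencies), "Hz"), "-",
      si_format(max(x$frequencies), "Hz"), "\n")
  cat("  Re[K] range: [", signif(min(x$re_k), 4), ",",
      signif(max(x$re_k), 4), "]\n")
  fx <- crossover_frequency(x$particle, x$medium,
                            f_min = min(x$frequencies),
                            f_max = max(x$frequencies))
  if (!is.na(fx)) cat("  crossover at", si_format(fx, "Hz"), "\n")
  invisible(x)
}

#' @export
plot.cm_spectrum <- function(x, ...) {
  graphics::plot(x$frequencies, x$re_k, type = "l", log = "x",
                 xlab = "Frequency (Hz)", ylab = "Re[K(f)]",
                 ylim = c(-0.55, 1.05), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' As-data-frame method for CM spectra
#' @param x a `cm_spectrum`.
#' @param ... unused.
#' @export
as.data.frame.cm_spectrum <- function(x, ...) {
  data.frame(frequency_hz = x$frequencies, re_k = Re(x$k_complex),
             im_k = Im(x$k_complex))
}

#' DEP crossover frequency
#'
#' The frequency at which \eqn{Re[K(f)]} changes sign, separating the
#' positive- and negative-DEP regimes.  Found by bisection after locating a
#' sign change on a log-spaced scan of \[`f_min`, `f_max`\]; `NA` if
#' \eqn{Re[K]} does not change sign on that range (both plateaus of the
#' single-relaxation spectrum have the same sign, or the pair is index
#' matched).
#'
#' @param particle a [spherical_particle()].
#' @param medium a [dielectric_material()].
#' @param f_min,f_max search range in Hz.
#' @param tol relative bisection tolerance on the root.
#' @return crossover frequency in Hz, or `NA_real_` if none exists.
#' @export
crossover_frequency <- function(particle, medium, f_min = 1e2, f_max = 1e12,
                                tol = 1e-9) {
  check_number(f_min, "f_min", min = 0, strict_min = TRUE)
  check_number(f_max, "f_max", min = f_min, strict_min = TRUE)
  rek <- function(f) Re(clausius_mossotti(particle, medium, f))
  grid <- exp(seq(log(f_min), log(f_max), length.out = 256))
  v <- rek(grid)
  # treat numerically-zero Re[K] (index-matched pair) as "no isolated crossing"
  if (all(abs(v) < 1e-12)) return(NA_real_)
  s <- sign(v)
  idx <- which(s[-1] * s[-length(s)] < 0)
  if (length(idx) == 0) return(NA_real_)
  lo <- grid[idx[1]]; hi <- grid[idx[1] + 1]
  stats::uniroot(rek, lower = lo, upper = hi, tol = lo * tol)$root
}

#' Dielectrophoretic force on a spherical particle
#'
#' \eqn{F_{DEP} = 2\pi r^3 \varepsilon_m\, Re[K(f)]\, \nabla |E|^2}: the force
#' is parallel to \eqn{\nabla|E|^2} for positive \eqn{Re[K]} (attraction to
#' field maxima at electrode edges) and antiparallel for negative
#' \eqn{Re[K]}.  \eqn{\varepsilon_m} is the real permittivity of the medium.
#'
#' @param particle a [spherical_particle()].
#' @param medium a [dielectric_material()].
#' @param f drive frequency in Hz.
#' @param grad_e_sq gradient of \eqn{|E|^2} in V^2/m^3 (numeric vector of any
#'   dimension).
#' @return force vector in N, same length as `grad_e_sq`.
#' @examples
#' ps <- spherical_particle(2.5e-6, dielectric_material(2.55, 1e-2))
#' water <- dielectric_material(80, 1e-4)
#' dep_force(ps, water, 1e5, c(1e13, 0))
#' @export
dep_force <- function(particle, medium, f, grad_e_sq) {
  stopifnot(inherits(particle, "spherical_particle"),
            inherits(medium, "dielectric_material"),
            is.numeric(grad_e_sq))
  re_k <- Re(clausius_mossotti(particle, medium, f))
  2 * pi * particle$radius^3 * medium$epsilon_r * EPS0 * re_k * grad_e_sq
}
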