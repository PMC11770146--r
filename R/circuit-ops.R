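# Closed-form circuit relations: capacitance estimates for the PCB
# structures, LC resonance, mutual inductance, quality factor and link
# efficiency of the inductive power link.

#' Capacitance of an interdigitated electrode array
#'
#' Parallel-plate estimate \eqn{C = n \cdot 2\varepsilon h l / d} treating each
#' of the `n` fingers as facing its neighbours across the gap `d` with plate
#' area `h * l` (copper height times finger length), in the permittivity of
#' the cover medium.
#'
#' @param array an [interdigitated_electrodes()].
#' @return capacitance in F.
#' @examples
#' arr <- interdigitated_electrodes(10, finger_length = 5e-3, gap = 125e-6)
#' electrode_capacitance(arr)  # ~19.8 pF with a water cover
#' @export
electrode_capacitance <- function(array) {
  stopifnot(inherits(array, "interdigitated_electrodes"))
  eps <- array$cover_medium$epsilon_r * EPS0
  array$n_fingers * 2 * eps * array$copper_height * array$finger_length /
    array$gap
}

#' Inter-layer (coil-plane) capacitance of the receiver board
#'
#' Annular parallel-plate estimate
#' \eqn{C = \varepsilon \pi (r_{outer}^2 - r_{inner}^2) / d_{coil}} for the
#' capacitance between the two copper planes of the coil, through the board
#' substrate.
#'
#' @param tank a [receiver_tank()].
#' @return capacitance in F.
#' @export
coil_plane_capacitance <- function(tank) {
  stopifnot(inherits(tank, "receiver_tank"))
  coil <- tank$coil
  if (coil$r_outer <= coil$r_inner)
    stop_invalid("r_outer must exceed r_inner")
  eps <- tank$substrate$epsilon_r * EPS0
  eps * pi * (coil$r_outer^2 - coil$r_inner^2) / tank$coil_plane_gap
}

#' Total tank capacitance
#'
#' \eqn{C = C_{electrode} + C_{coil} + C_{add}}.  If the tank carries a
#' measured parasitic override (e.g. inferred from a resonance curve), that
#' value replaces the two geometric estimates and only `c_added` is added.
#'
#' @param tank a [receiver_tank()].
#' @return capacitance in F.
#' @export
total_capacitance <- function(tank) {
  stopifnot(inherits(tank, "receiver_tank"))
  parasitic <- if (!is.null(tank$c_parasitic_override)) {
    tank$c_parasitic_override
  } else {
    electrode_capacitance(tank$electrodes) + coil_plane_capacitance(tank)
  }
  parasitic + tank$c_added
}

#' LC resonance frequency
#'
#' \eqn{f = 1 / (2\pi\sqrt{LC})}.
#'
#' @param L inductance in H (> 0).
#' @param C capacitance in F (> 0).
#' @return frequency in Hz.
#' @examples
#' resonance_frequency(4.6e-6, 35e-12)   # ~12.5 MHz
#' resonance_frequency(4.6e-6, 485e-12)  # ~3.37 MHz
#' @export
resonance_frequency <- function(L, C) {
  check_number(L, "L", min = 0, strict_min = TRUE)
  check_number(C, "C", min = 0, strict_min = TRUE)
  1 / (2 * pi * sqrt(L * C))
}

#' Capacitance from an observed resonance
#'
#' Algebraic inversion of the resonance formula:
#' \eqn{C = 1 / ((2\pi f)^2 L)}.  Round-trips with [resonance_frequency()] to
#' machine precision, and is the tool for inferring the parasitic capacitance
#' of a tank from a measured resonance peak.
#'
#' @param L inductance in H (> 0).
#' @param f observed resonance frequency in Hz (> 0).
#' @return capacitance in F.
#' @examples
#' capacitance_from_resonance(4.6e-6, 12.5e6)  # ~35 pF
#' @export
capacitance_from_resonance <- function(L, f) {
  check_number(L, "L", min = 0, strict_min = TRUE)
  check_number(f, "f", min = 0, strict_min = TRUE)
  1 / ((2 * pi * f)^2 * L)
}

#' Added capacitance required to hit a target resonance
#'
#' Inverts \eqn{f = 1/(2\pi\sqrt{L(C_{par} + C_{add})})} for the capacitor to
#' place across the receiver coil so that the tank resonates at `f_target`:
#' \eqn{C_{add} = 1/((2\pi f_{target})^2 L) - C_{par}}.  The target must lie
#' below the bare-tank resonance (adding capacitance can only lower it).
#'
#' @param L receiver inductance in H.
#' @param c_parasitic existing (parasitic) capacitance in F.
#' @param f_target desired resonance in Hz.
#' @return required added capacitance in F.
#' @examples
#' required_added_capacitance(4.6e-6, 35e-12, 3.37e6)  # ~450 pF
#' @export
required_added_capacitance <- function(L, c_parasitic, f_target) {
  check_number(L, "L", min = 0, strict_min = TRUE)
  check_number(c_parasitic, "c_parasitic", min = 0)
  check_number(f_target, "f_target", min = 0, strict_min = TRUE)
  c_add <- capacitance_from_resonance(L, f_target) - c_parasitic
  # a target exactly at the bare resonance is feasible with no capacitor;
  # forgive rounding at that boundary
  if (c_add < 0 && abs(c_add) <= 1e-9 * c_parasitic) c_add <- 0
  if (c_add < 0)
    stop_invalid("f_target (", si_format(f_target, "Hz"),
                 ") lies above the bare-tank resonance; ",
                 "added capacitance cannot raise the resonance frequency")
  c_add
}

#' Mutual inductance of two coupled coils
#'
#' \eqn{M = k\sqrt{L_1 L_2}}.
#'
#' @param L1,L2 coil inductances in H (> 0).
#' @param k coupling coefficient in \[0, 1\].
#' @return mutual inductance in H.
#' @export
mutual_inductance <- function(L1, L2, k) {
  check_number(L1, "L1", min = 0, strict_min = TRUE)
  check_number(L2, "L2", min = 0, strict_min = TRUE)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0 || k > 1)
    stop_domain("k must lie in [0, 1]")
  k * sqrt(L1 * L2)
}

#' Coil quality factor
#'
#' \eqn{Q = 2\pi f L / R}.
#'
#' @param f frequency in Hz (>= 0).
#' @param L inductance in H.
#' @param R series resistance in ohm (> 0; an ideal lossless coil has no
#'   finite Q).
#' @return dimensionless quality factor.
#' @export
quality_factor <- function(f, L, R) {
  check_number(f, "f", min = 0)
  check_number(L, "L", min = 0)
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop_domain("R must be > 0 (infinite Q is not represented)")
  2 * pi * f * L / R
}

#' Inductive link efficiency
#'
#' \eqn{\eta = k^2 Q_1 Q_2 / (1 + k^2 Q_1 Q_2)}: the logistic-form
#' approximation to the power-transfer efficiency of an inductive link in
#' terms of the coupling coefficient and the two coil quality factors.
#' Always in \[0, 1) and monotone non-decreasing in each argument.
#'
#' @param k coupling coefficient in \[0, 1\].
#' @param Q1,Q2 transmitter and receiver quality factors (>= 0).
#' @return efficiency as a fraction in \[0, 1).
#' @export
link_efficiency <- function(k, Q1, Q2) {
  check_number(k, "k", min = 0, max = 1)
  check_number(Q1, "Q1", min = 0)
  check_number(Q2, "Q2", min = 0)
  x <- k^2 * Q1 * Q2
  x / (1 + x)
}

#' Peak induced voltage in a secondary coil
#'
#' Faraday's law for a sinusoidal flux \eqn{\Phi(t) = \Phi_0 \sin(2\pi f t)}
#' through an `n_turns`-turn coil: the induced voltage \eqn{-N\,d\Phi/dt} has
#' peak amplitude \eqn{N \cdot 2\pi f \cdot \Phi_0}.
#'
#' @param n_turns number of turns in the secondary coil.
#' @param flux_amplitude peak magnetic flux \eqn{\Phi_0} in Wb.
#' @param f frequency in Hz.
#' @return peak voltage amplitude in V.
#' @export
induced_voltage_amplitude <- function(n_turns, flux_amplitude, f) {
  check_count(n_turns, "n_turns", min = 0L)
  check_number(flux_amplitude, "flux_amplitude", min = 0)
  check_number(f, "f", min = 0)
  n_turns * 2 * pi * f * flux_amplitude
}
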