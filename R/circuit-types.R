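# Constructors for the circuit-side domain objects: coils, electrode arrays,
# the receiver LC tank, the drive, and the inductive coupling.

#' Planar spiral PCB coil
#'
#' Geometric and electrical description of a planar spiral coil etched on a
#' PCB.  Inductance is taken as supplied (measured with an LCR meter or from a
#' datasheet); the package does not predict inductance from geometry.
#'
#' @param n_turns number of turns (>= 1).
#' @param inductance coil inductance in H (> 0).
#' @param series_resistance coil series resistance in ohm (>= 0).
#' @param r_outer,r_inner outer and inner radii in m (`r_outer > r_inner > 0`).
#' @param trace_width copper trace width in m.
#' @param turn_spacing gap between adjacent turns in m.
#' @param n_layers number of copper layers carrying turns.
#' @return An object of class `planar_coil`.
#' @examples
#' rx <- planar_coil(13, inductance = 4.6e-6, series_resistance = 2,
#'                   r_outer = 11e-3, r_inner = 5e-3)
#' @export
planar_coil <- function(n_turns, inductance, series_resistance = 1,
                        r_outer = 11e-3, r_inner = 5e-3,
                        trace_width = 1.8e-3, turn_spacing = 0.2e-3,
                        n_layers = 2L) {
  check_count(n_turns, "n_turns", min = 1L)
  check_number(inductance, "inductance", min = 0, strict_min = TRUE)
  check_number(series_resistance, "series_resistance", min = 0)
  check_number(r_outer, "r_outer", min = 0, strict_min = TRUE)
  check_number(r_inner, "r_inner", min = 0, strict_min = TRUE)
  if (r_outer <= r_inner) stop_invalid("r_outer must exceed r_inner")
  check_number(trace_width, "trace_width", min = 0, strict_min = TRUE)
  check_number(turn_spacing, "turn_spacing", min = 0)
  check_count(n_layers, "n_layers", min = 1L)
  structure(list(n_turns = as.integer(n_turns), inductance = inductance,
                 series_resistance = series_resistance,
                 r_outer = r_outer, r_inner = r_inner,
                 trace_width = trace_width, turn_spacing = turn_spacing,
                 n_layers = as.integer(n_layers)),
            class = "planar_coil")
}

#' @export
print.planar_coil <- function(x, ...) {
  cat("Planar spiral coil:", x$n_turns, "turns,",
      si_format(2 * x$r_outer, "m"), "OD /", si_format(2 * x$r_inner, "m"),
      "ID\n  L =", si_format(x$inductance, "H"),
      " R =", si_format(x$series_resistance, "ohm"), "\n")
  invisible(x)
}

#' Interdigitated electrode array
#'
#' Comb-like alternating-polarity finger electrodes on the PCB surface.  The
#' array contributes capacitance to the receiver tank and defines the field
#' geometry for DEP.
#'
#' @param n_fingers number of electrode fingers (>= 2).
#' @param finger_length finger length in m.
#' @param finger_width finger (trace) width in m.
#' @param gap gap between adjacent fingers in m.
#' @param copper_height copper layer thickness in m (default 35e-6, 1 oz
#'   copper).
#' @param cover_medium [dielectric_material()] above/between the fingers;
#'   defaults to water (`epsilon_r = 80`) since the fingers sit uncovered under
#'   the aqueous sample.
#' @return An object of class `interdigitated_electrodes`.
#' @export
interdigitated_electrodes <- function(n_fingers, finger_length = 5e-3,
                                      finger_width = 75e-6, gap = 125e-6,
                                      copper_height = 35e-6,
                                      cover_medium = dielectric_material(80, 0, "water")) {
  check_count(n_fingers, "n_fingers", min = 2L)
  check_number(finger_length, "finger_length", min = 0, strict_min = TRUE)
  check_number(finger_width, "finger_width", min = 0, strict_min = TRUE)
  check_number(gap, "gap", min = 0, strict_min = TRUE)
  check_number(copper_height, "copper_height", min = 0, strict_min = TRUE)
  stopifnot(inherits(cover_medium, "dielectric_material"))
  structure(list(n_fingers = as.integer(n_fingers),
                 finger_length = finger_length, finger_width = finger_width,
                 gap = gap, copper_height = copper_height,
                 cover_medium = cover_medium),
            class = "interdigitated_electrodes")
}

#' @export
print.interdigitated_electrodes <- function(x, ...) {
  cat("Interdigitated electrode array:", x$n_fingers, "fingers\n",
      " width =", si_format(x$finger_width, "m"),
      " gap =", si_format(x$gap, "m"),
      " length =", si_format(x$finger_length, "m"),
      " copper =", si_format(x$copper_height, "m"), "\n")
  invisible(x)
}

#' Receiver LC tank
#'
#' The receiver-side resonant network: the spiral coil in series with the
#' total capacitance formed by the electrode array, the coil's inter-layer
#' (board) capacitance, and an optional added SMD capacitor.
#'
#' @param coil receiver [planar_coil()].
#' @param electrodes [interdigitated_electrodes()] connected across the coil.
#' @param c_added added capacitor in F (>= 0; default 0).
#' @param coil_plane_gap separation of the two copper planes in m (default
#'   1e-3, the board thickness).
#' @param substrate board [dielectric_material()] (default FR4,
#'   `epsilon_r = 4.5`).
#' @param c_parasitic_override optional measured/inferred parasitic
#'   capacitance in F; when given it replaces the electrode + coil-plane
#'   estimate in [total_capacitance()].
#' @return An object of class `receiver_tank`.
#' @export
receiver_tank <- function(coil, electrodes, c_added = 0,
                          coil_plane_gap = 1e-3,
                          substrate = dielectric_material(4.5, 0, "FR4"),
                          c_parasitic_override = NULL) {
  stopifnot(inherits(coil, "planar_coil"),
            inherits(electrodes, "interdigitated_electrodes"))
  check_number(c_added, "c_added", min = 0)
  check_number(coil_plane_gap, "coil_plane_gap", min = 0, strict_min = TRUE)
  stopifnot(inherits(substrate, "dielectric_material"))
  if (!is.null(c_parasitic_override))
    check_number(c_parasitic_override, "c_parasitic_override", min = 0)
  structure(list(coil = coil, electrodes = electrodes, c_added = c_added,
                 coil_plane_gap = coil_plane_gap, substrate = substrate,
                 c_parasitic_override = c_parasitic_override),
            class = "receiver_tank")
}

#' @export
print.receiver_tank <- function(x, ...) {
  ct <- total_capacitance(x)
  cat("Receiver LC tank:\n  L =", si_format(x$coil$inductance, "H"),
      " C_total =", si_format(ct, "F"),
      " (C_add =", si_format(x$c_added, "F"), ")\n",
      " resonance =", si_format(resonance_frequency(x$coil$inductance, ct), "Hz"),
      "\n")
  invisible(x)
}

#' Transmitter drive signal
#'
#' The AC source applied to the transmitter coil.
#'
#' @param v_pp peak-to-peak source voltage in V (> 0).
#' @param frequency drive frequency in Hz (> 0).
#' @param source_resistance source output resistance in ohm (default 50).
#' @return An object of class `transmitter_drive`.
#' @export
transmitter_drive <- function(v_pp, frequency, source_resistance = 50) {
  check_number(v_pp, "v_pp", min = 0, strict_min = TRUE)
  check_number(frequency, "frequency", min = 0, strict_min = TRUE)
  check_number(source_resistance, "source_resistance", min = 0)
  structure(list(v_pp = v_pp, frequency = frequency,
                 source_resistance = source_resistance),
            class = "transmitter_drive")
}

#' @export
print.transmitter_drive <- function(x, ...) {
  cat("Drive:", si_format(x$v_pp, "Vpp"), "at", si_format(x$frequency, "Hz"),
      "(Rs =", si_format(x$source_resistance, "ohm"), ")\n")
  invisible(x)
}

#' Inductive coupling specification
#'
#' @param k coupling coefficient, dimensionless in \[0, 1\].
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(k) {
  check_number(k, "k", min = 0, max = 1)
  structure(list(k = k), class = "coupling_spec")
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat("Inductive coupling: k =", x$k, "\n")
  invisible(x)
}
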