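# Configuration-driven design workflow: load a device description from YAML,
# run the full design chain (capacitance -> resonance -> capacitor choice ->
# sweep -> CM factor -> field solve -> trap check), and write fixtures.

# Allowed keys per config section; key names carry their SI unit suffix.
.case_schema <- list(
  name = NULL,
  tx_coil = c("n_turns", "inductance_h", "series_resistance_ohm",
              "r_outer_m", "r_inner_m", "trace_width_m", "turn_spacing_m",
              "n_layers"),
  rx_coil = c("n_turns", "inductance_h", "series_resistance_ohm",
              "r_outer_m", "r_inner_m", "trace_width_m", "turn_spacing_m",
              "n_layers"),
  electrodes = c("n_fingers", "finger_length_m", "finger_width_m", "gap_m",
                 "copper_height_m", "cover_epsilon_r", "cover_sigma_s_per_m"),
  tank = c("c_added_f", "coil_plane_gap_m", "substrate_epsilon_r",
           "c_parasitic_override_f"),
  drive = c("v_pp", "frequency_hz", "source_resistance_ohm"),
  coupling = c("k"),
  particle = c("radius_m", "epsilon_r", "sigma_s_per_m"),
  medium = c("epsilon_r", "sigma_s_per_m"),
  suspension = c("viscosity_pa_s", "density_particle_kg_m3",
                 "density_medium_kg_m3"),
  spin = c("rpm", "radial_position_m"),
  unit_cell = c("channel_height_m")
)

validation_error <- function(path, msg) {
  stop(structure(class = c("depspin_validation", "error", "condition"),
                 list(message = paste0("config field ", path, ": ", msg),
                      call = NULL)))
}

need <- function(section, key, sec_name, positive = FALSE) {
  v <- section[[key]]
  path <- paste0(sec_name, ".", key)
  if (is.null(v)) validation_error(path, "missing")
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    validation_error(path, "must be a single finite number")
  if (positive && v <= 0) validation_error(path, "must be > 0")
  v
}

#' Load and validate a design case from a YAML file
#'
#' Reads a device description (coils, electrodes, tank, drive, coupling,
#' particle, medium, suspension, spin, unit cell) from YAML with SI values
#' and unit-suffixed key names (`inductance_h`, `gap_m`, ...).  Unknown
#' sections or keys are rejected; every validation error names the offending
#' field path.
#'
#' @param path path to the YAML file.
#' @return An object of class `design_case` holding the constructed package
#'   objects and the raw configuration.
#' @seealso [make_fixture()] for writing ready-made or randomized cases,
#'   [run_design()] for executing the design chain.
#' @export
load_case <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.case_schema))
  if (length(unknown))
    validation_error(unknown[1], "unknown section")
  for (sec in setdiff(names(.case_schema), "name")) {
    if (is.null(cfg[[sec]])) validation_error(sec, "missing section")
    bad <- setdiff(names(cfg[[sec]]), .case_schema[[sec]])
    if (length(bad))
      validation_error(paste0(sec, ".", bad[1]), "unknown key")
  }

  build_coil <- function(s, nm) {
    planar_coil(n_turns = need(s, "n_turns", nm, TRUE),
                inductance = need(s, "inductance_h", nm, TRUE),
                series_resistance = need(s, "series_resistance_ohm", nm),
                r_outer = need(s, "r_outer_m", nm, TRUE),
                r_inner = need(s, "r_inner_m", nm, TRUE),
                trace_width = need(s, "trace_width_m", nm, TRUE),
                turn_spacing = need(s, "turn_spacing_m", nm),
                n_layers = need(s, "n_layers", nm, TRUE))
  }
  wrap <- function(sec_name, expr) {
    tryCatch(expr, depspin_invalid = function(e)
      validation_error(sec_name, conditionMessage(e)))
  }

  tx <- wrap("tx_coil", build_coil(cfg$tx_coil, "tx_coil"))
  rx <- wrap("rx_coil", build_coil(cfg$rx_coil, "rx_coil"))
  el <- cfg$electrodes
  electrodes <- wrap("electrodes", interdigitated_electrodes(
    n_fingers = need(el, "n_fingers", "electrodes", TRUE),
    finger_length = need(el, "finger_length_m", "electrodes", TRUE),
    finger_width = need(el, "finger_width_m", "electrodes", TRUE),
    gap = need(el, "gap_m", "electrodes", TRUE),
    copper_height = need(el, "copper_height_m", "electrodes", TRUE),
    cover_medium = dielectric_material(
      need(el, "cover_epsilon_r", "electrodes", TRUE),
      need(el, "cover_sigma_s_per_m", "electrodes"))))
  tk <- cfg$tank
  tank <- wrap("tank", receiver_tank(
    rx, electrodes,
    c_added = need(tk, "c_added_f", "tank"),
    coil_plane_gap = need(tk, "coil_plane_gap_m", "tank", TRUE),
    substrate = dielectric_material(
      need(tk, "substrate_epsilon_r", "tank", TRUE), 0, "substrate"),
    c_parasitic_override = if (!is.null(tk$c_parasitic_override_f))
      need(tk, "c_parasitic_override_f", "tank") else NULL))
  dr <- cfg$drive
  drive <- wrap("drive", transmitter_drive(
    v_pp = need(dr, "v_pp", "drive", TRUE),
    frequency = need(dr, "frequency_hz", "drive", TRUE),
    source_resistance = need(dr, "source_resistance_ohm", "drive")))
  coupling <- wrap("coupling", coupling_spec(need(cfg$coupling, "k", "coupling")))
  pt <- cfg$particle
  particle <- wrap("particle", spherical_particle(
    need(pt, "radius_m", "particle", TRUE),
    dielectric_material(need(pt, "epsilon_r", "particle", TRUE),
                        need(pt, "sigma_s_per_m", "particle"))))
  md <- cfg$medium
  medium <- wrap("medium", dielectric_material(
    need(md, "epsilon_r", "medium", TRUE),
    need(md, "sigma_s_per_m", "medium")))
  sp <- cfg$suspension
  susp <- wrap("suspension", suspension(
    particle, medium,
    viscosity = need(sp, "viscosity_pa_s", "suspension", TRUE),
    density_particle = need(sp, "density_particle_kg_m3", "suspension", TRUE),
    density_medium = need(sp, "density_medium_kg_m3", "suspension", TRUE)))
  sn <- cfg$spin
  spin <- wrap("spin", spin_condition(
    rpm = need(sn, "rpm", "spin"),
    radial_position = need(sn, "radial_position_m", "spin", TRUE)))
  uc <- cfg$unit_cell
  unit_cell <- wrap("unit_cell", unit_cell_geometry(
    electrode_width = need(el, "finger_width_m", "electrodes", TRUE),
    gap = need(el, "gap_m", "electrodes", TRUE),
    channel_height = need(uc, "channel_height_m", "unit_cell", TRUE),
    copper_height = need(el, "copper_height_m", "electrodes", TRUE),
    applied_v_pp = drive$v_pp))

  structure(list(name = if (!is.null(cfg$name)) cfg$name else
                   basename(tools::file_path_sans_ext(path)),
                 tx_coil = tx, tank = tank, drive = drive,
                 coupling = coupling, suspension = susp, spin = spin,
                 unit_cell = unit_cell, config = cfg, path = path),
            class = "design_case")
}

#' @export
print.design_case <- function(x, ...) {
  cat("Design case '", x$name, "'\n", sep = "")
  print(x$tank); print(x$drive); print(x$coupling); print(x$spin)
  invisible(x)
}

#' Built-in and randomized design fixtures
#'
#' Writes a complete, valid YAML design case.  Named presets:
#' \describe{
#'   \item{`reference_disc`}{the resonant receiver disc: 13-turn 22 mm/10 mm
#'     coil at 4.6 uH, measured parasitic capacitance 35 pF, 450 pF added
#'     capacitor, 3.5 MHz drive.}
#'   \item{`polystyrene_beads`}{5 um polystyrene beads in DI water, 20 Vpp
#'     drive at 500 kHz (inside the homogeneous-sphere model's positive-DEP
#'     band), receiver tank tuned to the drive with a 22.1 nF capacitor,
#'     1000 RPM spin.}
#'   \item{`yeast_cells`}{baker's yeast in DI water, 3.5 MHz resonant drive.
#'     Yeast dielectric values are effective homogeneous placeholders
#'     (epsilon_r 60, sigma 0.2 S/m), suitable for sign/qualitative use
#'     only.}
#' }
#' With `name = "random"`, geometry and material values are drawn uniformly
#' from documented physical ranges using `seed` (recorded in the file), which
#' makes generation fully reproducible.
#'
#' @param name one of `"reference_disc"`, `"polystyrene_beads"`,
#'   `"yeast_cells"`, `"random"`.
#' @param dir directory to write into (default `tempdir()`).
#' @param seed integer seed for `name = "random"`.
#' @return the path of the written YAML file, invisibly a `design_case` via
#'   attribute; load it with [load_case()].
#' @export
make_fixture <- function(name = c("reference_disc", "polystyrene_beads",
                                  "yeast_cells", "random"),
                         dir = tempdir(), seed = 1L) {
  name <- match.arg(name)
  base <- list(
    name = name,
    tx_coil = list(n_turns = 13L, inductance_h = 4.6e-6,
                   series_resistance_ohm = 2.0, r_outer_m = 11e-3,
                   r_inner_m = 5e-3, trace_width_m = 1.8e-3,
                   turn_spacing_m = 0.2e-3, n_layers = 2L),
    rx_coil = list(n_turns = 13L, inductance_h = 4.6e-6,
                   series_resistance_ohm = 2.0, r_outer_m = 11e-3,
                   r_inner_m = 5e-3, trace_width_m = 1.8e-3,
                   turn_spacing_m = 0.2e-3, n_layers = 2L),
    electrodes = list(n_fingers = 10L, finger_length_m = 5e-3,
                      finger_width_m = 75e-6, gap_m = 125e-6,
                      copper_height_m = 35e-6, cover_epsilon_r = 80,
                      cover_sigma_s_per_m = 1e-4),
    tank = list(c_added_f = 450e-12, coil_plane_gap_m = 1e-3,
                substrate_epsilon_r = 4.5,
                c_parasitic_override_f = 35e-12),
    drive = list(v_pp = 20, frequency_hz = 3.5e6,
                 source_resistance_ohm = 50),
    coupling = list(k = 0.1),
    particle = list(radius_m = 2.5e-6, epsilon_r = 2.55,
                    sigma_s_per_m = 8e-3),
    medium = list(epsilon_r = 80, sigma_s_per_m = 1e-4),
    suspension = list(viscosity_pa_s = 1e-3,
                      density_particle_kg_m3 = 1050,
                      density_medium_kg_m3 = 1000),
    spin = list(rpm = 1000, radial_position_m = 25e-3),
    unit_cell = list(channel_height_m = 100e-6)
  )
  cfg <- base
  if (name == "polystyrene_beads") {
    # tank tuned to the 500 kHz drive (22.1 nF across the coil); closely
    # stacked coil pair
    cfg$tank$c_added_f <- 22.1e-9
    cfg$tank$c_parasitic_override_f <- 35e-12
    cfg$drive$frequency_hz <- 5e5
    cfg$drive$v_pp <- 20
    cfg$coupling$k <- 0.3
  } else if (name == "yeast_cells") {
    # effective homogeneous yeast placeholders; sign/qualitative use only
    cfg$particle$radius_m <- 2.5e-6
    cfg$particle$epsilon_r <- 60
    cfg$particle$sigma_s_per_m <- 0.2
    cfg$spin$rpm <- 0
    cfg$drive$v_pp <- 18
  } else if (name == "random") {
    set.seed(seed)
    cfg$name <- paste0("random_", seed)
    cfg$rx_coil$inductance_h <- stats::runif(1, 1e-6, 10e-6)
    cfg$tx_coil$inductance_h <- stats::runif(1, 1e-6, 10e-6)
    cfg$rx_coil$series_resistance_ohm <- stats::runif(1, 0.5, 10)
    cfg$tx_coil$series_resistance_ohm <- stats::runif(1, 0.5, 10)
    cfg$tank$c_added_f <- stats::runif(1, 0, 1e-9)
    cfg$tank$c_parasitic_override_f <- stats::runif(1, 10e-12, 100e-12)
    cfg$coupling$k <- stats::runif(1, 0.05, 0.5)
    cfg$electrodes$gap_m <- stats::runif(1, 50e-6, 250e-6)
    cfg$electrodes$finger_width_m <- stats::runif(1, 50e-6, 150e-6)
    cfg$particle$epsilon_r <- stats::runif(1, 2, 80)
    cfg$particle$sigma_s_per_m <- stats::runif(1, 0, 0.5)
    cfg$medium$epsilon_r <- stats::runif(1, 20, 80)
    cfg$medium$sigma_s_per_m <- stats::runif(1, 1e-5, 1e-2)
    cfg$seed <- NULL
  }
  path <- file.path(dir, paste0(cfg$name, ".yaml"))
  yaml::write_yaml(cfg, path, precision = 12)
  path
}

#' Run the full design chain on a case
#'
#' Executes, in order: capacitance estimates, bare-tank resonance,
#' recommended added capacitance for the drive frequency, tank resonance
#' with the actual added capacitor, a coupled-circuit frequency sweep, the
#' Clausius-Mossotti factor at the drive frequency, the unit-cell field
#' solve at the transferred (receiver) voltage, and a reference trap check
#' under the case's spin condition.  Any stage failure aborts with the stage
#' name attached.
#'
#' @param case a `design_case` from [load_case()].
#' @param resolution field-solver nodes per period.
#' @param sweep_points number of sweep frequencies.
#' @param t_max,wash_periods trajectory settings forwarded to
#'   [simulate_trajectory()].
#' @param seed integer recorded in the report (no stage is stochastic; the
#'   seed documents provenance for pipelines that add randomized inputs).
#' @return An object of class `design_report`.
#' @export
run_design <- function(case, resolution = 96, sweep_points = 301,
                       t_max = 150, wash_periods = 3, seed = NA_integer_) {
  stopifnot(inherits(case, "design_case"))
  report <- list(case = case$name, seed = seed,
                 config_hash = config_hash(case$config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(class = c("depspin_stage_error", "error", "condition"),
                     list(message = paste0("stage '", name, "' failed: ",
                                           conditionMessage(e)),
                          call = NULL, stage = name, partial = report)))
    })
  }

  L <- case$tank$coil$inductance
  report$c_electrode_f <- stage("capacitance",
    electrode_capacitance(case$tank$electrodes))
  report$c_coil_f <- stage("capacitance", coil_plane_capacitance(case$tank))
  report$c_parasitic_f <- stage("capacitance",
    if (!is.null(case$tank$c_parasitic_override))
      case$tank$c_parasitic_override else
      report$c_electrode_f + report$c_coil_f)
  report$c_total_f <- stage("capacitance", total_capacitance(case$tank))
  report$bare_resonance_hz <- stage("resonance",
    resonance_frequency(L, report$c_parasitic_f))
  report$resonance_hz <- stage("resonance",
    resonance_frequency(L, report$c_total_f))
  report$c_add_recommended_f <- stage("capacitor-choice",
    if (case$drive$frequency < report$bare_resonance_hz)
      required_added_capacitance(L, report$c_parasitic_f,
                                 case$drive$frequency) else 0)

  sw <- stage("sweep", sweep_receiver_voltage(
    case$tx_coil, case$tank, case$coupling, case$drive,
    f_min = report$resonance_hz * 0.4, f_max = report$resonance_hz * 2,
    n_points = sweep_points))
  report$sweep_peak_hz <- sw$resonance_peak
  i_drive <- which.min(abs(sw$frequencies - case$drive$frequency))
  report$v_rx_at_drive_pp <- stage("sweep", {
    d2 <- sweep_receiver_voltage(case$tx_coil, case$tank, case$coupling,
                                 case$drive, f_min = case$drive$frequency,
                                 f_max = case$drive$frequency * (1 + 1e-9),
                                 n_points = 2)
    d2$v_rx_pp[1]
  })
  report$v_rx_peak_pp <- max(sw$v_rx_pp)

  km <- stage("cm-factor", clausius_mossotti(
    case$suspension$particle, case$suspension$medium, case$drive$frequency))
  report$re_k_at_drive <- Re(km)
  report$im_k_at_drive <- Im(km)
  report$crossover_hz <- stage("cm-factor", crossover_frequency(
    case$suspension$particle, case$suspension$medium))

  geom <- case$unit_cell
  geom$applied_v_pp <- max(report$v_rx_at_drive_pp, 1e-12)
  field <- stage("field-solve", solve_unit_cell(geom, resolution = resolution))
  report$max_e_v_per_m <- sqrt(max(field$e_sq))

  tr <- stage("trap-check", simulate_trajectory(
    case$suspension, case$drive$frequency, field, case$spin,
    t_max = t_max, wash_periods = wash_periods))
  report$trap_outcome <- tr$outcome
  report$trap_final_speed_m_per_s <- tr$final_speed

  structure(report, class = "design_report")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp, precision = 12)
  unname(tools::md5sum(tmp))
}

#' @export
print.design_report <- function(x, ...) {
  cat("Design report for '", x$case, "'\n", sep = "")
  cat("  C_electrode ", si_format(x$c_electrode_f, "F"),
      "  C_coil ", si_format(x$c_coil_f, "F"),
      "  C_parasitic ", si_format(x$c_parasitic_f, "F"), "\n")
  cat("  C_total ", si_format(x$c_total_f, "F"),
      "  recommended C_add ", si_format(x$c_add_recommended_f, "F"), "\n")
  cat("  bare resonance ", si_format(x$bare_resonance_hz, "Hz"),
      "  tank resonance ", si_format(x$resonance_hz, "Hz"),
      "  sweep peak ", si_format(x$sweep_peak_hz, "Hz"), "\n")
  cat("  receiver voltage at drive ", si_format(x$v_rx_at_drive_pp, "Vpp"),
      " (peak ", si_format(x$v_rx_peak_pp, "Vpp"), ")\n")
  cat("  Re[K] at drive ", signif(x$re_k_at_drive, 4),
      "  crossover ", if (is.na(x$crossover_hz)) "none" else
        si_format(x$crossover_hz, "Hz"), "\n")
  cat("  trap check: ", x$trap_outcome, "\n")
  invisible(x)
}

#' Write a design report as JSON
#'
#' @param report a `design_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_design_report <- function(report, path) {
  stopifnot(inherits(report, "design_report"))
  out <- unclass(report)
  out$crossover_hz <- if (is.na(out$crossover_hz)) NULL else out$crossover_hz
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Path to an installed example design case
#'
#' @param name fixture file name (without extension); `NULL` lists available
#'   files.
#' @return file path, or a character vector of available names.
#' @export
depspin_example <- function(name = NULL) {
  dir <- system.file("extdata", package = "depspin")
  if (is.null(name))
    return(tools::file_path_sans_ext(list.files(dir, pattern = "\\.yaml$")))
  path <- file.path(dir, paste0(name, ".yaml"))
  if (!file.exists(path)) stop_invalid("no such example: ", name)
  path
}
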