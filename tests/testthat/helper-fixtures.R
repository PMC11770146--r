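# Shared builders for the test suite.  Field solves are memoised per
# (resolution, voltage, layout) so multiple test files can reuse them.

di_water <- function(sigma = 1e-4) dielectric_material(80, sigma, "DI water")

polystyrene_bead <- function(radius = 2.5e-6, sigma = 8e-3) {
  # sigma is the surface-conductance-dominated effective value for a small
  # bead in low-conductivity water
  spherical_particle(radius, dielectric_material(2.55, sigma), "bead")
}

bead_suspension <- function(sigma_p = 8e-3, sigma_m = 1e-4) {
  suspension(polystyrene_bead(sigma = sigma_p), di_water(sigma_m))
}

rx_coil_ref <- function(R = 2) planar_coil(13, 4.6e-6, R)

tank_ref <- function(c_added = 450e-12, c_parasitic = 35e-12, R = 2) {
  receiver_tank(rx_coil_ref(R), interdigitated_electrodes(10),
                c_added = c_added, c_parasitic_override = c_parasitic)
}

unit_cell_ref <- function(v_pp = 20)
  unit_cell_geometry(electrode_width = 75e-6, gap = 125e-6,
                     channel_height = 100e-6, applied_v_pp = v_pp)

.field_cache <- new.env(parent = emptyenv())
cached_field <- function(resolution = 64, v_pp = 20,
                         layout = "interdigitated") {
  key <- paste(resolution, v_pp, layout, sep = "_")
  if (is.null(.field_cache[[key]]))
    .field_cache[[key]] <- solve_unit_cell(unit_cell_ref(v_pp),
                                           resolution = resolution,
                                           layout = layout)
  .field_cache[[key]]
}
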