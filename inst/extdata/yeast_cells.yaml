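name: yeast_cells
tx_coil:
  n_turns: 13
  inductance_h: 4.6e-06
  series_resistance_ohm: 2.0
  r_outer_m: 0.011
  r_inner_m: 0.005
  trace_width_m: 0.0018
  turn_spacing_m: 0.0002
  n_layers: 2
rx_coil:
  n_turns: 13
  inductance_h: 4.6e-06
  series_resistance_ohm: 2.0
  r_outer_m: 0.011
  r_inner_m: 0.005
  trace_width_m: 0.0018
  turn_spacing_m: 0.0002
  n_layers: 2
electrodes:
  n_fingers: 10
  finger_length_m: 0.005
  finger_width_m: 7.5e-05
  gap_m: 0.000125
  copper_height_m: 3.5e-05
  cover_epsilon_r: 80.0
  cover_sigma_s_per_m: 0.0001
tank:
  c_added_f: 4.5e-10
  coil_plane_gap_m: 0.001
  substrate_epsilon_r: 4.5
  c_parasitic_override_f: 3.5e-11
drive:
  v_pp: 18.0
  frequency_hz: 3500000.0
  source_resistance_ohm: 50.0
coupling:
  k: 0.1
particle:
  radius_m: 2.5e-06
  epsilon_r: 60.0
  sigma_s_per_m: 0.2
medium:
  epsilon_r: 80.0
  sigma_s_per_m: 0.0001
suspension:
  viscosity_pa_s: 0.001
  density_particle_kg_m3: 1050.0
  density_medium_kg_m3: 1000.0
spin:
  rpm: 0.0
  radial_position_m: 0.025
unit_cell:
  channel_height_m: 0.0001
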