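# Closed-form circuit relations: capacitances, resonance, coupling, Q,
# efficiency, induced voltage.

test_that("electrode capacitance follows the parallel-plate formula", {
  arr <- interdigitated_electrodes(10, finger_length = 5e-3,
                                   finger_width = 75e-6, gap = 125e-6,
                                   copper_height = 35e-6,
                                   cover_medium = dielectric_material(80, 0))
  expect_equal(electrode_capacitance(arr), 19.83e-12, tolerance = 1e-3)
  # linear in the number of fingers
  arr2 <- interdigitated_electrodes(20, finger_length = 5e-3,
                                    finger_width = 75e-6, gap = 125e-6,
                                    copper_height = 35e-6,
                                    cover_medium = dielectric_material(80, 0))
  expect_equal(electrode_capacitance(arr2), 2 * electrode_capacitance(arr))
  expect_error(interdigitated_electrodes(10, copper_height = 0),
               class = "depspin_invalid")
})

test_that("coil-plane capacitance is the annular parallel-plate value", {
  tank <- receiver_tank(planar_coil(13, 4.6e-6, 2, r_outer = 11e-3,
                                    r_inner = 5e-3),
                        interdigitated_electrodes(10),
                        coil_plane_gap = 1e-3,
                        substrate = dielectric_material(4.5, 0))
  expect_equal(coil_plane_capacitance(tank), 12.02e-12, tolerance = 1e-3)
  # inverse in the plane gap
  tank2 <- tank; tank2$coil_plane_gap <- 0.5e-3
  expect_equal(coil_plane_capacitance(tank2), 2 * coil_plane_capacitance(tank))
  expect_error(planar_coil(13, 4.6e-6, 2, r_outer = 5e-3, r_inner = 5e-3),
               class = "depspin_invalid")
})

test_that("total capacitance sums the terms and honours a parasitic override", {
  arr <- interdigitated_electrodes(10, cover_medium = dielectric_material(80, 0))
  tank <- receiver_tank(planar_coil(13, 4.6e-6, 2), arr, c_added = 0)
  expect_equal(total_capacitance(tank),
               electrode_capacitance(arr) + coil_plane_capacitance(tank))
  expect_equal(total_capacitance(tank), 31.85e-12, tolerance = 1e-3)
  # inferred parasitic 35 pF plus a 450 pF SMD capacitor
  expect_equal(total_capacitance(tank_ref()), 485e-12)
})

test_that("resonance frequency and its inversion match the device numbers", {
  # bare tank: 4.6 uH with 35 pF parasitic resonates near 12.5 MHz
  expect_equal(signif(resonance_frequency(4.6e-6, 35e-12), 3), 12.5e6)
  # 450 pF added: resonance drops to 3.37 MHz
  expect_equal(resonance_frequency(4.6e-6, 485e-12), 3.37e6, tolerance = 1e-3)
  expect_equal(resonance_frequency(1, 1), 1 / (2 * pi))
  # inferring the parasitic capacitance from the measured bare resonance
  expect_equal(capacitance_from_resonance(4.6e-6, 12.5e6), 35.2e-12,
               tolerance = 1e-3)
  expect_equal(capacitance_from_resonance(1, 1 / (2 * pi)), 1)
  expect_error(resonance_frequency(0, 1), class = "depspin_invalid")
  expect_error(capacitance_from_resonance(4.6e-6, -1),
               class = "depspin_invalid")
})

test_that("resonance round-trips and is strictly decreasing in L and C", {
  set.seed(42)
  for (i in 1:50) {
    L <- 10^runif(1, -8, 0); C <- 10^runif(1, -13, -5)
    expect_equal(capacitance_from_resonance(L, resonance_frequency(L, C)), C,
                 tolerance = 1e-12)
    expect_lt(resonance_frequency(L * 1.5, C), resonance_frequency(L, C))
    expect_lt(resonance_frequency(L, C * 1.5), resonance_frequency(L, C))
  }
})

test_that("required added capacitance inverts the design equation", {
  expect_equal(required_added_capacitance(4.6e-6, 35e-12, 3.37e6), 450e-12,
               tolerance = 2e-3)
  bare <- resonance_frequency(4.6e-6, 35e-12)
  expect_equal(required_added_capacitance(4.6e-6, 35e-12, bare), 0,
               tolerance = 1e-9)
  expect_equal(required_added_capacitance(1, 0, 1 / (2 * pi)), 1)
  expect_error(required_added_capacitance(4.6e-6, 35e-12, 20e6),
               class = "depspin_invalid")
})

test_that("mutual inductance is k sqrt(L1 L2) with k bounded", {
  expect_equal(mutual_inductance(4.6e-6, 4.6e-6, 1), 4.6e-6)
  expect_equal(mutual_inductance(4.6e-6, 4.6e-6, 0), 0)
  expect_equal(mutual_inductance(4.6e-6, 4.6e-6, 0.2), 0.92e-6)
  expect_error(mutual_inductance(1e-6, 1e-6, 1.2), class = "depspin_domain")
  expect_error(mutual_inductance(1e-6, 1e-6, -0.1), class = "depspin_domain")
})

test_that("quality factor is 2 pi f L / R", {
  expect_equal(quality_factor(3.5e6, 4.6e-6, 5), 20.23, tolerance = 1e-3)
  expect_equal(quality_factor(0, 4.6e-6, 5), 0)
  expect_equal(quality_factor(7e6, 4.6e-6, 5),
               2 * quality_factor(3.5e6, 4.6e-6, 5))
  expect_error(quality_factor(1e6, 4.6e-6, 0), class = "depspin_domain")
})

test_that("link efficiency is bounded in [0, 1) and monotone", {
  expect_equal(link_efficiency(0, 100, 100), 0)
  expect_equal(link_efficiency(0.1, 10, 10), 0.5)  # k^2 Q1 Q2 = 1
  expect_equal(link_efficiency(0.3, 20, 20), 0.973, tolerance = 1e-3)
  set.seed(7)
  for (i in 1:50) {
    k <- runif(1); q1 <- runif(1, 0, 500); q2 <- runif(1, 0, 500)
    eta <- link_efficiency(k, q1, q2)
    expect_gte(eta, 0); expect_lt(eta, 1)
    expect_gte(link_efficiency(min(k * 1.1, 1), q1, q2), eta)
    expect_gte(link_efficiency(k, q1 * 1.1, q2), eta)
    expect_gte(link_efficiency(k, q1, q2 * 1.1), eta)
  }
})

test_that("induced voltage amplitude follows Faraday's law", {
  expect_equal(induced_voltage_amplitude(13, 0, 3.5e6), 0)
  expect_equal(induced_voltage_amplitude(1, 1, 1 / (2 * pi)), 1)
  expect_equal(induced_voltage_amplitude(13, 1e-9, 3.5e6), 0.286,
               tolerance = 1e-3)
})
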