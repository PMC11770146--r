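# Overdamped particle transport: force composition, the drift oracle,
# trap/wash classification and the holding-voltage bisection.

test_that("net force composes DEP and centrifugal terms correctly", {
  susp <- bead_suspension()
  fm <- cached_field(64)
  spin0 <- spin_condition(0)
  pos <- c(100e-6, 30e-6)
  # no spin: net force is exactly the DEP force
  fq <- field_at(fm, pos[1], pos[2])
  expect_identical(net_force(susp, 5e5, fm, spin0, pos),
                   dep_force(susp$particle, susp$medium, 5e5, fq$grad_e_sq))
  # no field, no spin: nothing
  fm0 <- depspin:::rescale_voltage(fm, 0)
  expect_identical(net_force(susp, 5e5, fm0, spin0, pos), c(0, 0))
  # neutrally buoyant particle feels no centrifugal force
  neutral <- suspension(susp$particle, susp$medium,
                        density_particle = 1000, density_medium = 1000)
  expect_identical(net_force(neutral, 5e5, fm0, spin_condition(3000), pos),
                   c(0, 0))
})

test_that("forces carry the exact V^2 and omega^2 R scalings", {
  susp <- bead_suspension()
  spin1 <- spin_condition(1000); spin2 <- spin_condition(2000)
  f1 <- cached_field(64, v_pp = 20)
  f2 <- depspin:::rescale_voltage(f1, 40)
  pos <- c(90e-6, 40e-6)
  spin0 <- spin_condition(0)
  expect_equal(net_force(susp, 5e5, f2, spin0, pos),
               4 * net_force(susp, 5e5, f1, spin0, pos))
  fm0 <- depspin:::rescale_voltage(f1, 0)
  expect_equal(net_force(susp, 5e5, fm0, spin2, pos),
               4 * net_force(susp, 5e5, fm0, spin1, pos))
  r2 <- spin_condition(1000, radial_position = 50e-3)
  expect_equal(net_force(susp, 5e5, fm0, r2, pos),
               2 * net_force(susp, 5e5, fm0, spin1, pos))
})

test_that("zero-voltage drift reproduces the Stokes terminal velocity", {
  susp <- bead_suspension()
  fm <- cached_field(64)
  spin <- spin_condition(1000)
  tr <- simulate_trajectory(susp, 5e5, fm, spin, v_pp = 0,
                            t_max = 200, wash_periods = 2)
  expect_identical(tr$outcome, "washed")
  v_theory <- (2 / 9) * (1050 - 1000) * spin$omega^2 * 25e-3 *
    (2.5e-6)^2 / 1e-3
  expect_equal(tr$drift / tr$t_end, v_theory, tolerance = 0.01)
})

test_that("no voltage and no spin leaves the particle stationary", {
  susp <- bead_suspension()
  fm <- cached_field(64)
  tr <- simulate_trajectory(susp, 5e5, fm, spin_condition(0), v_pp = 0,
                            start = c(150e-6, 50e-6), t_max = 5)
  expect_identical(tr$outcome, "undecided")
  n <- nrow(tr$positions)
  expect_equal(tr$positions[n, ], tr$positions[1, ], tolerance = 1e-12)
})

test_that("outcome is robust to halving the time step", {
  susp <- bead_suspension()
  fm <- cached_field(64)
  spin <- spin_condition(1000)
  for (v in c(0, 20)) {
    t1 <- simulate_trajectory(susp, 5e5, fm, spin, v_pp = v,
                              dt = 5e-3, t_max = 150, wash_periods = 2)
    t2 <- simulate_trajectory(susp, 5e5, fm, spin, v_pp = v,
                              dt = 2.5e-3, t_max = 150, wash_periods = 2)
    expect_identical(t1$outcome, t2$outcome)
  }
})

test_that("trapping fraction grows with voltage and needs a field at all", {
  susp <- bead_suspension()
  fm <- cached_field(64)
  spin <- spin_condition(1000)
  fractions <- vapply(c(0, 5, 12, 20), function(v) {
    trapping_map(susp, 5e5, fm, spin, n_starts = 6, v_pp = v,
                 t_max = 150, wash_periods = 2)$fraction_trapped
  }, numeric(1))
  expect_identical(fractions[1], 0)          # nothing to hold the beads
  expect_true(all(diff(fractions) >= 0))     # monotone in drive voltage
  expect_gt(fractions[4], 0)                 # the applied signal traps
})

test_that("without spin a strongly driven pDEP particle always traps", {
  susp <- bead_suspension()
  fm <- cached_field(64)
  tm <- trapping_map(susp, 5e5, fm, spin_condition(0), n_starts = 4,
                     v_pp = 100, t_max = 150)
  expect_identical(tm$fraction_trapped, 1)
})

test_that("holding voltage scales with the square root of omega^2 R", {
  susp <- bead_suspension()
  fm <- cached_field(64)
  v1 <- minimum_holding_voltage(susp, 5e5, fm, spin_condition(1000),
                                t_max = 150, wash_periods = 2)
  v2 <- minimum_holding_voltage(susp, 5e5, fm, spin_condition(2000),
                                t_max = 150, wash_periods = 2)
  expect_equal(v2 / v1, 2, tolerance = 0.08)
  # without spin, any small voltage eventually traps the reference particle
  v0 <- minimum_holding_voltage(susp, 5e5, fm, spin_condition(0),
                                t_max = 150, wash_periods = 2)
  expect_lt(v0, 2)
})

test_that("negative-DEP particles cannot be edge-trapped", {
  # lossless polystyrene is nDEP across the whole spectrum in water
  susp <- bead_suspension(sigma_p = 0)
  fm <- cached_field(64)
  v <- minimum_holding_voltage(susp, 1e7, fm, spin_condition(1000),
                               v_cap = 100, t_max = 30, wash_periods = 2)
  expect_identical(v, Inf)
})
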