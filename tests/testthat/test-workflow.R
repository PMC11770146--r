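# Config loading/validation, fixtures, and the end-to-end design chain.

test_that("shipped fixtures load and validate", {
  for (nm in c("reference_disc", "polystyrene_beads", "yeast_cells")) {
    path <- make_fixture(nm, dir = withr::local_tempdir())
    case <- load_case(path)
    expect_s3_class(case, "design_case")
    expect_identical(case$name, nm)
  }
  # installed copies match the generator
  expect_setequal(depspin_example(),
                  c("reference_disc", "polystyrene_beads", "yeast_cells"))
  ref <- load_case(depspin_example("reference_disc"))
  expect_identical(ref$tank$coil$n_turns, 13L)
  expect_equal(ref$tank$coil$inductance, 4.6e-6)
  expect_equal(ref$tank$c_added, 450e-12)
  expect_equal(ref$tank$coil$r_outer, 11e-3)
  expect_equal(ref$tank$coil$r_inner, 5e-3)
})

test_that("validation errors name the offending field", {
  dir <- withr::local_tempdir()
  path <- make_fixture("reference_disc", dir = dir)
  cfg <- yaml::read_yaml(path)
  cfg$electrodes$gap_m <- -1
  bad <- file.path(dir, "bad.yaml")
  yaml::write_yaml(cfg, bad)
  expect_error(load_case(bad), "electrodes.gap_m",
               class = "depspin_validation")
  cfg <- yaml::read_yaml(path)
  cfg$drive$wattage <- 5
  yaml::write_yaml(cfg, bad)
  expect_error(load_case(bad), "drive.wattage", class = "depspin_validation")
  cfg <- yaml::read_yaml(path)
  cfg$spin <- NULL
  yaml::write_yaml(cfg, bad)
  expect_error(load_case(bad), "spin", class = "depspin_validation")
})

test_that("fixture generation is deterministic and round-trips", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- make_fixture("random", dir = d1, seed = 5)
  p2 <- make_fixture("random", dir = d2, seed = 5)
  expect_identical(readLines(p1), readLines(p2))
  # every randomized fixture passes validation
  for (s in 1:5) {
    p <- make_fixture("random", dir = d1, seed = s)
    expect_s3_class(load_case(p), "design_case")
  }
  # structural round-trip: dump(load(x)) == load(x)
  case <- load_case(p1)
  p3 <- file.path(d1, "roundtrip.yaml")
  yaml::write_yaml(case$config, p3, precision = 12)
  expect_identical(load_case(p3)$config, case$config)
})

test_that("the design chain reproduces the reference-device resonances", {
  case <- load_case(make_fixture("reference_disc",
                                 dir = withr::local_tempdir()))
  rep <- run_design(case, resolution = 64, sweep_points = 201,
                    t_max = 60, wash_periods = 2)
  expect_equal(rep$resonance_hz, 3.37e6, tolerance = 1e-3)
  expect_equal(rep$bare_resonance_hz, 12.5e6, tolerance = 5e-3)
  expect_equal(rep$c_add_recommended_f, 450e-12, tolerance = 0.01)
  # internal consistency: reported resonance recomputes from reported C
  expect_equal(resonance_frequency(case$tank$coil$inductance, rep$c_total_f),
               rep$resonance_hz, tolerance = 1e-9)
  # yeast is pulled to the electrode edges at the resonant drive (pDEP)
  yeast <- load_case(make_fixture("yeast_cells",
                                  dir = withr::local_tempdir()))
  expect_gt(Re(clausius_mossotti(yeast$suspension$particle,
                                 yeast$suspension$medium,
                                 yeast$drive$frequency)), 0)
})

test_that("an uncoupled case transfers nothing and washes", {
  dir <- withr::local_tempdir()
  path <- make_fixture("polystyrene_beads", dir = dir)
  cfg <- yaml::read_yaml(path)
  cfg$coupling$k <- 0
  k0 <- file.path(dir, "k0.yaml")
  yaml::write_yaml(cfg, k0)
  rep <- run_design(load_case(k0), resolution = 64, sweep_points = 101,
                    t_max = 120, wash_periods = 2)
  expect_identical(rep$v_rx_at_drive_pp, 0)
  expect_identical(rep$trap_outcome, "washed")
})

test_that("reports are deterministic and stage failures are labelled", {
  dir <- withr::local_tempdir()
  case <- load_case(make_fixture("reference_disc", dir = dir))
  r1 <- run_design(case, resolution = 48, sweep_points = 101,
                   t_max = 30, wash_periods = 2, seed = 7)
  r2 <- run_design(case, resolution = 48, sweep_points = 101,
                   t_max = 30, wash_periods = 2, seed = 7)
  j1 <- file.path(dir, "r1.json"); j2 <- file.path(dir, "r2.json")
  write_design_report(r1, j1); write_design_report(r2, j2)
  expect_identical(readLines(j1), readLines(j2))
  # a tank with no capacitance at all cannot resonate: the resonance stage
  # aborts and says so
  cfg <- yaml::read_yaml(make_fixture("reference_disc", dir = dir))
  cfg$tank$c_added_f <- 0
  cfg$tank$c_parasitic_override_f <- 0
  bad <- file.path(dir, "noc.yaml")
  yaml::write_yaml(cfg, bad)
  expect_error(run_design(load_case(bad)), "resonance",
               class = "depspin_stage_error")
})

test_that("the CLI front end exits zero on success and nonzero on bad input", {
  cli <- system.file("cli", "depspin", package = "depspin")
  rscript <- file.path(R.home("bin"), "Rscript")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  out <- withr::local_tempfile(fileext = ".json")
  ok <- system2(rscript, c(cli, "design-resonance",
                           "--inductance-h", "4.6e-6",
                           "--c-parasitic-f", "35e-12",
                           "--target-hz", "3.37e6"),
                stdout = out, stderr = FALSE, env = env)
  expect_identical(ok, 0L)
  parsed <- jsonlite::fromJSON(readLines(out))
  expect_equal(parsed$c_add_f, 450e-12, tolerance = 0.01)
  bad <- system2(rscript, c(cli, "sweep", "--config", "/nonexistent.yaml",
                            "--fmin", "1e6", "--fmax", "2e6"),
                 stdout = FALSE, stderr = FALSE, env = env)
  expect_gt(bad, 0L)
  none <- system2(rscript, c(cli, "not-a-command"),
                  stdout = FALSE, stderr = FALSE, env = env)
  expect_gt(none, 0L)
})
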