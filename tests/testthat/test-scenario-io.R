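# Scenario presets, validation, YAML round trips, and the CLI.

test_that("presets carry the documented default parameterization", {
  sc <- ncycle_scenario("table3_high_fixation")
  expect_equal(sc$degassing$alpha_m, 0.2)
  expect_equal(sc$alpha_a, 0.2)
  expect_equal(sc$subduction$D, 1e8)          # 100 Ma turnover
  expect_equal(sc$subduction$eps, 0.05)
  expect_equal(sc$bulk_n, 3.4e19)
  expect_equal(sc$dt, 5000)
  expect_equal(sc$lightning$nox_at_pal, 4e10)
  lo <- ncycle_scenario("table3_low_fixation")
  expect_equal(lo$lightning$nox_at_pal, 2.6e6)
  expect_equal(ncycle_scenario("low_budget")$bulk_n, 9.3e18)
  expect_true(all(c("table3_high_fixation", "subduction_50Ma",
                    "constant_forcings") %in% ncycle_presets()$preset))
})

test_that("subduction presets differ from the default only in D", {
  a <- ncycle_scenario("table3_high_fixation")
  b <- ncycle_scenario("subduction_50Ma")
  expect_equal(b$subduction$D, 5e7)
  b$subduction$D <- a$subduction$D
  b$preset <- a$preset
  expect_equal(unclass(b), unclass(a))
})

test_that("unknown presets and fields fail with helpful listings", {
  expect_error(ncycle_scenario("no_such_world"), "available presets")
  expect_error(ncycle_scenario(frobnicate = 1), "unknown scenario field")
})

test_that("out-of-range parameters are rejected with the field named", {
  expect_error(ncycle_scenario(alpha_a = 1.5), "alpha_a")
  expect_error(ncycle_scenario(dt = 0), "dt")
  expect_error(ncycle_scenario(bulk_n = -1), "bulk_n")
  expect_error(ncycle_scenario(erosion_rate = -1e-5), "erosion_rate")
  expect_error(degassing_params(alpha_m = 2), "alpha_m")
  expect_error(subduction_params(eps = -0.1), "eps")
  expect_error(subduction_params(D = 0), "D")
  expect_error(freundlich_params(n = 0), "n")
  expect_error(henry_params(K = 0), "K")
  expect_error(lightning_rates("high", nox_at_pal = -1), "non-negative")
})

test_that("scenarios round-trip through YAML files", {
  sc <- ncycle_scenario("subduction_150Ma",
                        erosion_rate = 1e-5,
                        ocean_volume_change_pct = -30)
  path <- tempfile(fileext = ".yaml")
  save_scenario(sc, path)
  back <- load_scenario(path)
  expect_equal(back, sc)
  # loading a preset name directly also works
  expect_equal(load_scenario("table3_low_fixation"),
               ncycle_scenario("table3_low_fixation"))
})

test_that("cli run writes a conservative trajectory and a manifest", {
  out <- tempfile("ncycle-run-")
  cfg <- tempfile(fileext = ".yaml")
  save_scenario(ncycle_scenario(t_end = 2e8, stride = 1000L), cfg)
  status <- suppressMessages(
    cli_main(c("run", "--config", cfg, "--seed", "4", "--out", out)))
  expect_identical(status, 0L)
  csv <- read.csv(file.path(out, "trajectory.csv"), comment.char = "#")
  sc <- load_scenario(cfg)
  expected <- sc$bulk_n + nitrocycle:::comet_integral(sc$comet, 2e8)
  expect_equal(csv$total_kg[nrow(csv)], expected, tolerance = 1e-6)
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$seed, 4)
  expect_equal(manifest$parameters$subduction$D, 1e8)
  # the manifest parameters + seed reproduce the run (text round trip
  # limits the comparison to the written precision)
  again <- ncycle_run(sc, seed = 4)
  expect_equal(unname(final_state(again)[1]), csv$atm_n2[nrow(csv)],
               tolerance = 1e-12)
  expect_identical(again$states, ncycle_run(sc, seed = 4)$states)
})

test_that("cli sweep emits one row per grid point and presets lists them all", {
  out <- tempfile("ncycle-sweep-")
  cfg <- tempfile(fileext = ".yaml")
  save_scenario(ncycle_scenario(t_end = 1e8, stride = 1000L), cfg)
  status <- suppressMessages(
    cli_main(c("sweep", "--config", cfg, "--param", "degassing.alpha_m",
               "--grid", "0:1:0.1", "--n", "2", "--seed", "1",
               "--out", out)))
  expect_identical(status, 0L)
  csv <- read.csv(file.path(out, "sweep.csv"), comment.char = "#")
  expect_identical(nrow(csv), 11L)
  expect_equal(csv$value, seq(0, 1, 0.1))
  listing <- capture.output(status2 <- suppressMessages(cli_main("presets")))
  expect_identical(status2, 0L)
  expect_true(any(grepl("table3_high_fixation", listing)))
  expect_identical(suppressMessages(cli_main(c("run", "--bogus"))), 1L)
  expect_identical(suppressMessages(cli_main("explode")), 1L)
})
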