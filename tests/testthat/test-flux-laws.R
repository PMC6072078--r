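# Individual flux parameterizations: printed reference values, limits,
# and linearity in the source mass.

test_that("cometary delivery follows the late-accretion forcing", {
  f <- decay_forcing(2.4e8, 2.4e5, 1.5e8)
  expect_equal(comet_delivery(0, f), 2.4e8)
  expect_equal(comet_delivery(100 * f$tau, f), 2.4e5, tolerance = 1e-10)
  # analytic 4.5-Gyr integral: F0*T + (F1 - F0)*tau*(1 - exp(-T/tau))
  expect_equal(nitrocycle:::comet_integral(f, 4.5e9), 3.70440e16,
               tolerance = 1e-5)
})

test_that("impact fixation scales with atmospheric content and splits by alpha_a", {
  expect_equal(sum(impact_fixation(0, 4e18, alpha_a = 0.2)), 4.7e9)
  expect_equal(sum(impact_fixation(0, 2e18, alpha_a = 0.2)), 2.35e9)  # 0.5 PAL
  expect_equal(impact_fixation(0, 4e18, alpha_a = 0.2),
               c(nox = 0.8 * 4.7e9, nhx = 0.2 * 4.7e9))
  expect_equal(impact_fixation(0, 0, 0.2), c(nox = 0, nhx = 0))
  expect_equal(sum(impact_fixation(100 * 1.5e8, 4e18, 0.2)), 4.7e6,
               tolerance = 1e-10)
})

test_that("lightning fixation reproduces both regime rate pairs and PAL scaling", {
  expect_equal(lightning_fixation(4e18, lightning_rates("high")),
               c(nox = 4e10, nhx = 1.6e7))
  expect_equal(lightning_fixation(4e18, lightning_rates("low")),
               c(nox = 2.6e6, nhx = 1e3))
  expect_equal(lightning_fixation(8e18, lightning_rates("high")),
               c(nox = 8e10, nhx = 3.2e7))
  expect_equal(lightning_fixation(0, lightning_rates("high")),
               c(nox = 0, nhx = 0))
})

test_that("hydrothermal circulation converts all NOx and 0.1% of N2", {
  expect_equal(hydrothermal_conversion(1e-7, 1e17, 1e16),
               c(nox_to_nhx = 1e10, n2_to_nhx = 1e6))
  expect_equal(hydrothermal_conversion(0, 1e17, 1e16),
               c(nox_to_nhx = 0, n2_to_nhx = 0))
  expect_equal(hydrothermal_conversion(1e-7, 0, 0),
               c(nox_to_nhx = 0, n2_to_nhx = 0))
})

test_that("subduction partitions the sediment flux by accretion efficiency", {
  p <- subduction_params(D = 1e8, eps = 0.05)
  f <- subduction_fluxes(1e18, p)
  expect_equal(f, c(to_uma = 9.5e9, to_ccr = 5e8))
  expect_identical(sum(f), 1e18 / 1e8)
  expect_equal(subduction_fluxes(1e18, subduction_params(1e8, 0))[["to_ccr"]], 0)
  expect_equal(subduction_fluxes(1e18, subduction_params(1e8, 1))[["to_uma"]], 0)
})

test_that("erosion carries the eroded volume fraction of crustal nitrogen", {
  expect_equal(erosion_flux(1.7e18, 5e-5, 1.725e14, 6.9e18), 2.125e9)
  expect_equal(erosion_flux(1.7e18, 5e-5, 0, 0), 0)
  expect_equal(erosion_flux(1.7e18, 1e-4, 1.725e14, 6.9e18),
               2 * erosion_flux(1.7e18, 5e-5, 1.725e14, 6.9e18))
})

test_that("degassing splits the upper-mantle flux by alpha_m", {
  d <- degassing_params(alpha_m = 0.19, f_uma_ref = 2.0e8)
  f <- degassing_fluxes(d$m_uma_ref, 0, d)
  expect_equal(f[["arc"]], 3.8e7)
  expect_equal(f[["morb"]], 1.62e8)
  expect_equal(degassing_fluxes(0, 0, d), c(arc = 0, morb = 0, hotspot = 0))
  d1 <- degassing_params(alpha_m = 1)
  expect_equal(degassing_fluxes(1e18, 0, d1)[["morb"]], 0)
  # linear scaling with mantle content
  expect_equal(degassing_fluxes(2 * d$m_uma_ref, 0, d)[["arc"]], 2 * 3.8e7)
})

test_that("mantle mixing is a concentration-equalizing exchange", {
  # equal concentrations: zero net flux
  f <- mantle_mixing_fluxes(1e18, 2e18, 1e-8, rock_uma = 1e24, rock_lma = 2e24)
  expect_equal(f[["lma_to_uma"]], f[["uma_to_lma"]])
  expect_equal(mantle_mixing_fluxes(1e18, 2e18, 0, 1e24, 2e24),
               c(lma_to_uma = 0, uma_to_lma = 0))
})

test_that("two-box mixing relaxes to equal concentration at the analytic rate", {
  r <- 1e-9; Ru <- 1e24; Rl <- 2e24; M <- 3e18
  lambda <- r * (Ru + Rl)^2 / (Ru * Rl)
  m_u_star <- M * Ru / (Ru + Rl)
  # forward-Euler integration of the isolated two-box exchange
  dt <- 1e5; m_u <- 0; m_l <- M
  prev_gap <- Inf
  for (i in seq_len(5000)) {
    f <- mantle_mixing_fluxes(m_u, m_l, r, Ru, Rl)
    net <- f[["lma_to_uma"]] - f[["uma_to_lma"]]
    m_u <- m_u + net * dt; m_l <- m_l - net * dt
    gap <- abs(m_l / Rl - m_u / Ru)
    expect_lt(gap, prev_gap)  # monotone convergence
    prev_gap <- gap
  }
  t <- 5000 * dt
  expect_equal(m_u, m_u_star * (1 - exp(-lambda * t)), tolerance = 1e-3)
})

test_that("metamorphic release is a standalone order-of-magnitude diagnostic", {
  est <- metamorphic_flux_estimate(1.7e18, 0.75, 1e9)
  expect_equal(est, 1.275e9)
  expect_gt(est, 1e9); expect_lt(est, 1e10)  # order 1e9
  expect_equal(metamorphic_flux_estimate(1.7e18, 0, 1e9), 0)
  expect_equal(metamorphic_flux_estimate(1.7e18, 0.75, 1e8), 10 * est)
})

test_that("every network flux is non-negative and degree-1 in its source", {
  sc <- ncycle_scenario()
  set.seed(7)
  for (i in 1:20) {
    s <- reservoir_state(setNames(runif(8, 0, 1e19), nitrocycle:::NCYCLE_POOLS))
    t <- runif(1, 0, 4.5e9)
    fl <- flux_vector(s, sc, t)
    expect_true(all(fl$flux >= 0))
    # doubling the state doubles every flux except the external comet term
    fl2 <- flux_vector(reservoir_state(2 * s), sc, t)
    internal <- fl$edge != "comet"
    expect_equal(fl2$flux[internal], 2 * fl$flux[internal], tolerance = 1e-12)
    expect_equal(fl2$flux[!internal], fl$flux[!internal])
  }
})

test_that("fluxes vanish with their source reservoirs", {
  sc <- ncycle_scenario()
  zero <- reservoir_state()
  fl <- flux_vector(zero, sc, 1e9)
  expect_true(all(fl$flux[fl$edge != "comet"] == 0))
  expect_gt(fl$flux[fl$edge == "comet"], 0)
})
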