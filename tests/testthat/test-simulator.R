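# State container, single steps, full runs, conservation and accuracy.

test_that("reservoir states are validated and canonically ordered", {
  s <- reservoir_state(atm_n2 = 4e18, oce_n2 = 2.4e16)
  expect_named(s, nitrocycle:::NCYCLE_POOLS)
  expect_equal(total_nitrogen(s), 4e18 + 2.4e16)
  # reordering on input
  shuffled <- s[rev(names(s))]
  expect_equal(reservoir_state(shuffled), s)
  expect_error(reservoir_state(atm_n2 = -1), "atm_n2")
  expect_error(reservoir_state(uma_nhx = NaN), "uma_nhx")
  expect_equal(total_nitrogen(reservoir_state()), 0)
})

test_that("PAL conversion is linear and anchored at 4e18 kg", {
  expect_equal(to_pal(4e18), 1)
  expect_equal(to_pal(0), 0)
  expect_equal(to_pal(2e18), 0.5)
})

test_that("random initial states sit on the bulk-N simplex, reproducibly", {
  s1 <- random_initial_state(3.4e19, seed = 11)
  s2 <- random_initial_state(3.4e19, seed = 11)
  expect_identical(s1, s2)
  expect_equal(sum(s1), 3.4e19, tolerance = 1e-12)
  expect_true(all(s1 > 0))
  expect_false(isTRUE(all.equal(s1, random_initial_state(3.4e19, seed = 12))))
})

test_that("initial-state generator has symmetric-Dirichlet moments", {
  n <- 1e4
  fracs <- matrix(0, n, 8)
  for (i in seq_len(n)) fracs[i, ] <- random_initial_state(1, seed = i)
  se <- sqrt(1 / 8 * 7 / 8 / 9 / n)  # Dirichlet(1,...,1) component sd / sqrt(n)
  expect_true(all(abs(colMeans(fracs) - 1 / 8) < 3 * se))
})

test_that("the generator does not disturb the session RNG", {
  set.seed(123); before <- .Random.seed
  invisible(random_initial_state(1e19, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("a zero step or an empty quiescent system changes nothing", {
  sc <- no_flux_scenario()
  s <- random_initial_state(1e19, seed = 3)
  expect_identical(ncycle_step(s, sc, t = 0, dt = 0), s)
  zero <- reservoir_state()
  expect_equal(ncycle_step(zero, sc, t = 1e9), zero)
})

test_that("one Euler step under lightning alone fixes the expected mass", {
  sc <- lightning_only_scenario("high")
  s0 <- equilibrate_state(reservoir_state(atm_n2 = 4e18), sc)
  n2_0 <- s0[["atm_n2"]] + s0[["oce_n2"]]
  s1 <- ncycle_step(s0, sc, t = 0)
  fixed <- (4e10 + 1.6e7) * (s0[["atm_n2"]] / 4e18) * sc$dt
  gained <- sum(s1[c("oce_nox", "oce_nhx", "sed_nhx")]) -
            sum(s0[c("oce_nox", "oce_nhx", "sed_nhx")])
  expect_equal(gained, fixed, tolerance = 1e-12)
  expect_equal(s1[["atm_n2"]] + s1[["oce_n2"]], n2_0 - fixed, tolerance = 1e-12)
})

test_that("with all fluxes disabled the trajectory is constant", {
  sc <- no_flux_scenario(t_end = 1e8, stride = 100L)
  init <- equilibrate_state(random_initial_state(1e19, seed = 5), sc)
  traj <- ncycle_run(sc, init = init)
  for (k in seq_len(nrow(traj$states)))
    expect_equal(traj$states[k, ], init, tolerance = 1e-12)
})

test_that("compiled and reference R engines integrate identically", {
  sc <- ncycle_scenario(t_end = 5e5, stride = 10L)  # 100 steps
  init <- random_initial_state(3.4e19, seed = 8)
  a <- ncycle_run(sc, init = init, engine = "C", record_fluxes = TRUE)
  b <- ncycle_run(sc, init = init, engine = "R", record_fluxes = TRUE)
  expect_equal(a$times, b$times)
  expect_equal(a$states, b$states, tolerance = 1e-12)
  expect_equal(a$fluxes, b$fluxes, tolerance = 1e-12)
})

test_that("flux limiting keeps pools non-negative under violent steps", {
  sc <- ncycle_scenario(dt = 1e7, t_end = 1e9, stride = 1L,
                        hydrothermal = decay_forcing(3e-4, 1e-4, 1.5e8))
  set.seed(99)
  for (i in 1:10) {
    raw <- runif(8, 0, 1)
    s <- reservoir_state(setNames(raw / sum(raw) * 3.4e19,
                                  nitrocycle:::NCYCLE_POOLS))
    s1 <- ncycle_step(s, sc, t = 0)
    expect_true(all(s1 >= 0))
    expect_true(all(is.finite(s1)))
  }
  traj <- ncycle_run(sc, seed = 1)
  expect_true(all(traj$states >= 0))
})

test_that("total nitrogen is conserved without external delivery", {
  sc <- ncycle_scenario(comet = decay_forcing(0, 0, 1.5e8),
                        t_end = 5e8, stride = 1000L)
  traj <- ncycle_run(sc, seed = 2)
  expect_lt(traj$conservation_error, 1e-11)
})

test_that("with delivery on the budget follows the analytic comet integral", {
  sc <- ncycle_scenario(t_end = 1e9, stride = 1000L)
  traj <- ncycle_run(sc, seed = 2)
  total0 <- sum(traj$states[1, ])
  expected <- total0 + nitrocycle:::comet_integral(sc$comet, 1e9)
  expect_equal(sum(final_state(traj)), expected, tolerance = 1e-6)
})

test_that("a small perturbation of one pool decays back to the attractor", {
  sc <- ncycle_scenario(t_end = 1e9)
  init <- random_initial_state(3.4e19, seed = 21)
  pert <- init
  pert[["atm_n2"]] <- pert[["atm_n2"]] * (1 + 1e-6)
  a <- final_state(ncycle_run(sc, init = init))
  b <- final_state(ncycle_run(sc, init = reservoir_state(pert)))
  rel <- abs(b - a) / pmax(a, 1)
  expect_lt(max(rel), 1e-6)
})

test_that("the stepper reports non-finite states by pool name", {
  sc <- ncycle_scenario()
  s <- reservoir_state(atm_n2 = 4e18)
  s[["oce_nhx"]] <- NaN
  expect_error(ncycle_step(s, sc, t = 0), "oce_nhx")
})
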