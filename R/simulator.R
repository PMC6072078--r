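#' Reservoir state vector
#'
#' The model state holds eight nitrogen pools in kg N: atmospheric N2,
#' the three dissolved ocean species (N2, NOx, NHx), adsorbed marine
#' sediment NHx, continental crust NHx, and upper/lower mantle NHx.
#'
#' @param x either a named numeric vector with (a permutation of) the
#'   eight pool names, or missing to use the individual arguments.
#' @param atm_n2,oce_n2,oce_nox,oce_nhx,sed_nhx,ccr_nhx,uma_nhx,lma_nhx
#'   pool masses in kg N, `>= 0` and finite.
#' @return A named numeric vector in canonical pool order.
#' @examples
#' reservoir_state(atm_n2 = 4e18, oce_n2 = 2.4e16)
#' @export
reservoir_state <- function(x, atm_n2 = 0, oce_n2 = 0, oce_nox = 0,
                            oce_nhx = 0, sed_nhx = 0, ccr_nhx = 0,
                            uma_nhx = 0, lma_nhx = 0) {
  if (missing(x)) {
    x <- c(atm_n2 = atm_n2, oce_n2 = oce_n2, oce_nox = oce_nox,
           oce_nhx = oce_nhx, sed_nhx = sed_nhx, ccr_nhx = ccr_nhx,
           uma_nhx = uma_nhx, lma_nhx = lma_nhx)
  } else {
    if (is.null(names(x)) && length(x) == 8L) names(x) <- NCYCLE_POOLS
    if (!all(NCYCLE_POOLS %in% names(x)))
      stop("state must carry the pool names: ", paste(NCYCLE_POOLS, collapse = ", "))
    x <- x[NCYCLE_POOLS]
  }
  bad <- !is.finite(x) | x < 0
  if (any(bad))
    stop("invalid (negative or non-finite) pool mass in: ",
         paste(NCYCLE_POOLS[bad], collapse = ", "))
  x
}

#' Random initial nitrogen distribution
#'
#' Draws the eight pools uniformly on the simplex (a symmetric
#' Dirichlet with concentration 1) and scales them to the bulk budget,
#' emulating ignorance about the nitrogen distribution just after
#' planetary differentiation.  Deterministic given `seed`; the RNG state
#' of the session is left untouched.
#'
#' @param bulk_n total nitrogen to distribute, kg, `> 0`.
#' @param seed integer seed.
#' @return A [reservoir_state()] whose pools sum to `bulk_n`.
#' @export
random_initial_state <- function(bulk_n, seed) {
  if (!is.numeric(bulk_n) || bulk_n <= 0) stop("'bulk_n' must be positive")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  e <- rexp(8L)
  reservoir_state(setNames(e / sum(e) * bulk_n, NCYCLE_POOLS))
}

#' Total nitrogen in a state
#'
#' @param s a [reservoir_state()].
#' @return Sum of all pools, kg N.  Invariant under both equilibrium
#'   partitions and under every internal flux.
#' @export
total_nitrogen <- function(s) sum(reservoir_state(s))

#' Convert a nitrogen mass to present atmospheric levels (PAL)
#'
#' @param mass mass in kg N (vectorized).
#' @param pal_mass mass of one PAL, kg N (modern atmospheric N2
#'   inventory, 4e18 kg).
#' @return `mass / pal_mass`, dimensionless.
#' @export
to_pal <- function(mass, pal_mass = 4e18) {
  if (pal_mass <= 0) stop("'pal_mass' must be positive")
  mass / pal_mass
}

#' Advance the state by one time step (reference R engine)
#'
#' One explicit-Euler step: (1) evaluate all flux laws at the current
#' state and time, (2) limit each pool's total outflow to the mass it
#' actually holds over `dt`, (3) update the pools, (4) re-impose the two
#' instantaneous equilibria (Henry's law on total N2, the Freundlich
#' isotherm on mobile NHx).  [ncycle_run()] uses a compiled
#' implementation of exactly this step; this R version is its
#' cross-check and is convenient for inspecting single steps.
#'
#' @param state a [reservoir_state()].
#' @param scenario an [ncycle_scenario()].
#' @param t model time, yr.
#' @param dt step length, yr (defaults to the scenario's); `dt = 0`
#'   returns the state unchanged.
#' @return The updated [reservoir_state()].
#' @export
ncycle_step <- function(state, scenario, t, dt = scenario$dt) {
  stopifnot(inherits(scenario, "ncycle_scenario"))
  s <- reservoir_state(state)
  if (!is.finite(t) || t < 0) stop("model time 't' must be non-negative")
  if (dt == 0) return(s)

  fl <- flux_vector(s, scenario, t)
  f <- setNames(fl$flux, fl$edge)

  # limit outflows so no pool can be driven negative within one step
  limit <- function(pool, edges) {
    out <- sum(f[edges])
    if (out * dt > s[[pool]]) f[edges] <<- f[edges] * s[[pool]] / (out * dt)
  }
  limit("atm_n2",  c("impact_nox", "impact_nhx", "lightning_nox", "lightning_nhx"))
  limit("oce_n2",  "hydrothermal_n2")
  limit("oce_nox", "hydrothermal_nox")
  limit("sed_nhx", c("subduction_uma", "subduction_ccr"))
  limit("ccr_nhx", "erosion")
  limit("uma_nhx", c("arc", "morb", "mixing_uma_lma"))
  limit("lma_nhx", c("hotspot", "mixing_lma_uma"))

  d <- c(
    atm_n2  = f[["arc"]] - f[["impact_nox"]] - f[["impact_nhx"]] -
              f[["lightning_nox"]] - f[["lightning_nhx"]],
    oce_n2  = -f[["hydrothermal_n2"]],
    oce_nox = f[["impact_nox"]] + f[["lightning_nox"]] - f[["hydrothermal_nox"]],
    oce_nhx = f[["comet"]] + f[["impact_nhx"]] + f[["lightning_nhx"]] +
              f[["hydrothermal_nox"]] + f[["hydrothermal_n2"]] +
              f[["erosion"]] + f[["morb"]] + f[["hotspot"]],
    sed_nhx = -f[["subduction_uma"]] - f[["subduction_ccr"]],
    ccr_nhx = f[["subduction_ccr"]] - f[["erosion"]],
    uma_nhx = f[["subduction_uma"]] + f[["mixing_lma_uma"]] -
              f[["mixing_uma_lma"]] - f[["arc"]] - f[["morb"]],
    lma_nhx = f[["mixing_uma_lma"]] - f[["mixing_lma_uma"]] - f[["hotspot"]]
  )
  tot <- sum(s)
  s <- s + d * dt
  # a fully drained pool can land a rounding error below zero
  s[s < 0 & s > -(1e-12 * tot + 1e-9)] <- 0
  if (any(!is.finite(s) | s < 0))
    stop("non-finite or negative pool after step at t = ", t, ": ",
         paste(NCYCLE_POOLS[!is.finite(s) | s < 0], collapse = ", "))

  v <- ocean_volume_at(scenario, t)
  s[c("atm_n2", "oce_n2")] <-
    partition_n2(s[["atm_n2"]] + s[["oce_n2"]], scenario$henry, v)
  s[c("oce_nhx", "sed_nhx")] <-
    partition_nhx(s[["oce_nhx"]] + s[["sed_nhx"]], scenario$freundlich, v)
  s
}

#' Run a single trajectory
#'
#' Integrates the flux network with explicit Euler steps of `dt` from
#' `t = 0` (planet formation) to `t_end` (nominally 4.5 Gyr, the
#' present), recording the state every `stride` steps.  A conservation
#' audit compares the total nitrogen along the trajectory against the
#' closed-form time integral of the cometary source (the only external
#' input); the worst relative deviation is stored in the result.
#'
#' @param scenario an [ncycle_scenario()].
#' @param init optional initial [reservoir_state()]; by default a random
#'   distribution of the scenario's `bulk_n` from `seed`.
#' @param seed integer seed for the random initial state (required when
#'   `init` is missing).
#' @param engine `"C"` (compiled, default) or `"R"` (reference
#'   implementation looping over [ncycle_step()]; slow, for testing).
#' @param record_fluxes if `TRUE`, store the full flux vector at every
#'   sampled time for auditing.
#' @return An object of class `"ncycle_trajectory"`: a list with
#'   `times` (yr), `states` (matrix, one row per sample, kg N),
#'   `fluxes` (optional matrix of edge fluxes, kg N/yr), the scenario,
#'   the seed, and `conservation_error` (max relative audit deviation).
#' @examples
#' \donttest{
#' traj <- ncycle_run(ncycle_scenario(), seed = 1)
#' summary(traj)
#' }
#' @export
ncycle_run <- function(scenario, init = NULL, seed = NULL,
                       engine = c("C", "R"), record_fluxes = FALSE) {
  stopifnot(inherits(scenario, "ncycle_scenario"))
  engine <- match.arg(engine)
  if (is.null(init)) {
    if (is.null(seed)) stop("either 'init' or 'seed' must be supplied")
    init <- random_initial_state(scenario$bulk_n, seed)
  } else {
    init <- reservoir_state(init)
  }
  nsteps <- as.integer(round(scenario$t_end / scenario$dt))
  stride <- as.integer(scenario$stride)

  if (engine == "C") {
    res <- run_core(init, scenario_par_list(scenario), scenario$dt, nsteps,
                    stride, record_fluxes)
    times <- res$times
    states <- res$states
    fluxes <- if (record_fluxes) res$fluxes else NULL
  } else {
    idx <- unique(c(seq(0L, nsteps - 1L, by = stride), nsteps))
    times <- idx * scenario$dt
    states <- matrix(NA_real_, length(idx), 8L,
                     dimnames = list(NULL, NCYCLE_POOLS))
    fluxes <- if (record_fluxes)
      matrix(NA_real_, length(idx), nrow(NCYCLE_EDGES),
             dimnames = list(NULL, NCYCLE_EDGES$edge)) else NULL
    s <- init
    k <- 1L
    for (i in seq_len(nsteps + 1L) - 1L) {
      t <- i * scenario$dt
      if (k <= length(idx) && i == idx[k]) {
        states[k, ] <- s
        if (record_fluxes) fluxes[k, ] <- flux_vector(s, scenario, t)$flux
        k <- k + 1L
      }
      if (i < nsteps) s <- ncycle_step(s, scenario, t)
    }
  }
  colnames(states) <- NCYCLE_POOLS
  if (!is.null(fluxes)) colnames(fluxes) <- NCYCLE_EDGES$edge

  expected <- total_nitrogen(init) + comet_integral(scenario$comet, times)
  cons_err <- max(abs(rowSums(states) - expected) / expected)

  structure(list(times = times, states = states, fluxes = fluxes,
                 scenario = scenario, seed = seed,
                 conservation_error = cons_err),
            class = "ncycle_trajectory")
}

# closed-form integral of the cometary forcing from 0 to t
comet_integral <- function(f, t) {
  f$F0 * t + (f$F1 - f$F0) * f$tau * (1 - exp(-t / f$tau))
}

# flatten a scenario for the compiled stepper
scenario_par_list <- function(sc) {
  list(
    comet = unlist(sc$comet[c("F1", "F0", "tau")]),
    impact = unlist(sc$impact[c("F1", "F0", "tau")]),
    hydrothermal = unlist(sc$hydrothermal[c("F1", "F0", "tau")]),
    mixing = unlist(sc$mantle_mixing[c("F1", "F0", "tau")]),
    lightning = c(sc$lightning$nox_at_pal, sc$lightning$nhx_at_pal),
    alpha_a = sc$alpha_a,
    degassing = c(sc$degassing$alpha_m, sc$degassing$f_uma_ref,
                  sc$degassing$f_lma_ref, sc$degassing$m_uma_ref,
                  sc$degassing$m_lma_ref),
    subduction = c(sc$subduction$D, sc$subduction$eps),
    erosion_rate = sc$erosion_rate,
    growth = c(sc$growth$mode == "two_phase", sc$growth$early_rate,
               sc$growth$late_rate, sc$growth$breakpoint,
               sc$growth$present_volume, sc$growth$mean_thickness),
    henry = c(sc$henry$K, sc$henry$ocean_volume, sc$henry$pal_mass,
              sc$henry$p_ref, sc$henry$molar_mass_n2),
    freundlich = c(sc$freundlich$Kf, sc$freundlich$n,
                   sc$freundlich$sediment_solid_mass),
    rock = c(sc$rock_uma, sc$rock_lma),
    ocean_volume_change_pct = sc$ocean_volume_change_pct
  )
}

#' @export
print.ncycle_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("nitrocycle trajectory (preset: ", x$scenario$preset, ")\n", sep = "")
  cat(sprintf("  %d samples over %.3g yr (dt = %g yr)\n",
              n, x$times[n], x$scenario$dt))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  cat(sprintf("  conservation audit: max relative deviation %.2e\n",
              x$conservation_error))
  cat("  final state (PAL):\n")
  print(round(to_pal(x$states[n, ], x$scenario$henry$pal_mass), 4))
  invisible(x)
}

#' @export
summary.ncycle_trajectory <- function(object, ...) {
  pal <- object$scenario$henry$pal_mass
  out <- list(
    preset = object$scenario$preset,
    t_end = object$times[length(object$times)],
    initial_pal = to_pal(object$states[1, ], pal),
    final_pal = to_pal(object$states[nrow(object$states), ], pal),
    mean_pal = average_balance(object),
    total_initial = sum(object$states[1, ]),
    total_final = sum(object$states[nrow(object$states), ]),
    conservation_error = object$conservation_error
  )
  class(out) <- "summary.ncycle_trajectory"
  out
}

#' @export
print.summary.ncycle_trajectory <- function(x, ...) {
  cat("nitrocycle trajectory summary (preset: ", x$preset, ")\n", sep = "")
  tab <- rbind(initial = x$initial_pal, `time mean` = x$mean_pal,
               final = x$final_pal)
  print(round(tab, 4))
  cat(sprintf("total N: %.4g -> %.4g kg (conservation audit %.2e)\n",
              x$total_initial, x$total_final, x$conservation_error))
  invisible(x)
}

#' @export
as.data.frame.ncycle_trajectory <- function(x, ...) {
  pal <- x$scenario$henry$pal_mass
  df <- data.frame(time_yr = x$times, x$states, check.names = FALSE)
  palmat <- to_pal(x$states, pal)
  colnames(palmat) <- paste0(NCYCLE_POOLS, "_pal")
  cbind(df, as.data.frame(palmat), total_kg = rowSums(x$states))
}

#' Plot a trajectory
#'
#' Pool masses (in PAL) against model time on a log y-axis.
#'
#' @param x an `ncycle_trajectory`.
#' @param pools which pools to draw (default all eight).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ncycle_trajectory <- function(x, pools = NCYCLE_POOLS, ...) {
  pal <- to_pal(x$states[, pools, drop = FALSE], x$scenario$henry$pal_mass)
  pal[pal <= 0] <- NA
  matplot(x$times / 1e9, pal, type = "l", lty = 1,
          col = seq_along(pools), log = "y",
          xlab = "model time (Gyr)", ylab = "nitrogen (PAL)", ...)
  legend("bottomright", legend = pools, col = seq_along(pools),
         lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
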