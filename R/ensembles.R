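#' Random-initial-condition ensemble
#'
#' Runs `n_members` trajectories of the same scenario from independent
#' random initial distributions of the bulk nitrogen budget (member `i`
#' uses seed `seed + i`).  Because every flux law is linear in its
#' source mass, trajectories contract onto a common evolutionary track;
#' the ensemble spread quantifies how fast the system forgets its
#' initial conditions.
#'
#' @param scenario an [ncycle_scenario()].
#' @param n_members number of members, `>= 2`.
#' @param seed integer base seed.
#' @return An object of class `"ncycle_ensemble"`: list with `members`
#'   (trajectories), `times`, `seeds`, and the scenario.
#' @examples
#' \donttest{
#' e <- ncycle_ensemble(ncycle_scenario(), n_members = 10, seed = 1)
#' collapse_time(e, "atm_n2", tol = 0.05) / 1e6  # Ma
#' }
#' @seealso [collapse_time()], [average_balance()]
#' @export
ncycle_ensemble <- function(scenario, n_members = 10, seed = 1) {
  stopifnot(inherits(scenario, "ncycle_scenario"))
  if (n_members < 2) stop("'n_members' must be at least 2")
  seeds <- as.integer(seed) + seq_len(n_members)
  members <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    members[[i]] <- tryCatch(
      ncycle_run(scenario, seed = seeds[i]),
      error = function(e) stop("ensemble member ", i, " (seed ", seeds[i],
                               ") failed: ", conditionMessage(e)))
  }
  structure(list(members = members, times = members[[1]]$times,
                 seeds = seeds, scenario = scenario),
            class = "ncycle_ensemble")
}

#' Simulate ensembles directly from a scenario
#'
#' `simulate()` on a scenario is shorthand for [ncycle_ensemble()].
#'
#' @param object an [ncycle_scenario()].
#' @param nsim number of ensemble members.
#' @param seed integer base seed.
#' @param ... unused.
#' @return An `ncycle_ensemble`.
#' @importFrom stats simulate
#' @export
simulate.ncycle_scenario <- function(object, nsim = 10, seed = 1, ...) {
  ncycle_ensemble(object, n_members = nsim, seed = seed)
}

# member x time matrix for one pool
ensemble_pool_matrix <- function(e, pool) {
  pool <- match.arg(pool, NCYCLE_POOLS)
  t(vapply(e$members, function(m) m$states[, pool], numeric(length(e$times))))
}

# relative ensemble spread (max - min) / mean, per sampled time
ensemble_spread <- function(e, pool) {
  m <- ensemble_pool_matrix(e, pool)
  mn <- colMeans(m)
  spread <- apply(m, 2L, max) - apply(m, 2L, min)
  ifelse(mn > 0, spread / mn, 0)
}

#' Ensemble collapse time
#'
#' Earliest sampled time after which the relative ensemble spread
#' ((max - min) / mean) of a pool stays below `tol` for the rest of the
#' run; `Inf` if the spread never settles.  In the high-fixation regime
#' trajectories join the common track within a few hundred Myr, while in
#' the low-fixation regime the atmosphere exchanges nitrogen so slowly
#' that collapse takes several Gyr.
#'
#' @param e an [ncycle_ensemble()].
#' @param pool pool name (default atmospheric N2).
#' @param tol relative spread tolerance, `> 0` (default 5%).
#' @return Collapse time in years, or `Inf`.
#' @export
collapse_time <- function(e, pool = "atm_n2", tol = 0.05) {
  stopifnot(inherits(e, "ncycle_ensemble"))
  if (tol <= 0) stop("'tol' must be positive")
  below <- ensemble_spread(e, pool) < tol
  stays <- rev(cumprod(rev(below))) > 0  # below tol from here to the end
  if (!any(stays)) return(Inf)
  e$times[which(stays)[1L]]
}

#' Time-averaged mass balance
#'
#' Time-weighted (trapezoidal) mean of every pool over a window,
#' expressed in PAL.  For an ensemble the member trajectories are
#' averaged pointwise first.  The default window is the full run; pass
#' e.g. `window = c(4.0e9, 4.5e9)` for a late-epoch average
#' characterizing the tracked steady state after initial-condition
#' collapse.
#'
#' @param x an `ncycle_trajectory` or `ncycle_ensemble`.
#' @param window `c(t_start, t_end)` in years within the sampled span.
#' @return Named numeric vector of pool means in PAL.
#' @export
average_balance <- function(x, window = NULL) {
  if (inherits(x, "ncycle_ensemble")) {
    states <- Reduce(`+`, lapply(x$members, `[[`, "states")) / length(x$members)
    times <- x$times
    pal <- x$scenario$henry$pal_mass
  } else if (inherits(x, "ncycle_trajectory")) {
    states <- x$states
    times <- x$times
    pal <- x$scenario$henry$pal_mass
  } else stop("'x' must be an ncycle_trajectory or ncycle_ensemble")
  if (is.null(window)) window <- range(times)
  if (length(window) != 2L || window[1] >= window[2])
    stop("'window' must be c(t_start, t_end) with t_start < t_end")
  if (window[1] < min(times) || window[2] > max(times))
    stop("'window' must lie within the sampled span [",
         min(times), ", ", max(times), "] yr")
  keep <- times >= window[1] & times <= window[2]
  if (sum(keep) < 2L) stop("'window' contains fewer than two samples")
  tt <- times[keep]
  ss <- states[keep, , drop = FALSE]
  w <- diff(tt)
  avg <- (colSums(ss[-nrow(ss), , drop = FALSE] * w) +
          colSums(ss[-1L, , drop = FALSE] * w)) / (2 * sum(w))
  to_pal(avg, pal)
}

#' Atmospheric fraction of the bulk silicate nitrogen budget
#'
#' A planetary diagnostic comparing atmospheres across bodies: Earth's
#' modern value is 4.0e18 / 3.4e19 = 0.12, Venus' is 0.76, and Mars'
#' 1.63e-4.
#'
#' @param m_atm atmospheric N mass, kg.
#' @param bulk_silicate_n bulk silicate (non-core) N budget, kg, `> 0`.
#' @return Dimensionless ratio.
#' @export
atmospheric_fraction <- function(m_atm, bulk_silicate_n) {
  if (any(bulk_silicate_n <= 0)) stop("'bulk_silicate_n' must be positive")
  m_atm / bulk_silicate_n
}

#' Sweepable scenario parameters
#'
#' @param scenario an [ncycle_scenario()].
#' @return Character vector of dotted paths addressing the scalar
#'   parameters that [ncycle_sweep()] can vary.  For the decay forcings,
#'   the pseudo-field `.rate` (e.g. `"mantle_mixing.rate"`) sets a
#'   constant forcing (`F0 = F1 = value`).
#' @export
sweepable_params <- function(scenario) {
  stopifnot(inherits(scenario, "ncycle_scenario"))
  out <- character()
  for (nm in names(scenario)) {
    x <- scenario[[nm]]
    if (inherits(x, "decay_forcing")) {
      out <- c(out, paste0(nm, c(".F1", ".F0", ".tau", ".rate")))
    } else if (is.list(x)) {
      num <- names(x)[vapply(x, function(v) is.numeric(v) && length(v) == 1L,
                             logical(1))]
      out <- c(out, paste0(nm, ".", num))
    } else if (is.numeric(x) && length(x) == 1L && nm != "stride") {
      out <- c(out, nm)
    }
  }
  out
}

set_param <- function(scenario, path, value) {
  known <- sweepable_params(scenario)
  if (!path %in% known)
    stop("unknown or non-sweepable parameter '", path, "'; sweepable: ",
         paste(known, collapse = ", "))
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  if (length(parts) == 1L) {
    scenario[[parts]] <- value
  } else if (parts[2L] == "rate") {
    f <- scenario[[parts[1L]]]
    scenario[[parts[1L]]] <- decay_forcing(F1 = value, F0 = value, tau = f$tau)
  } else {
    obj <- unclass(scenario[[parts[1L]]])
    obj[[parts[2L]]] <- value
    cls <- class(scenario[[parts[1L]]])
    ctor <- switch(cls[1L],
                   decay_forcing = decay_forcing,
                   lightning_rates = NULL,
                   degassing_params = degassing_params,
                   subduction_params = subduction_params,
                   henry_params = henry_params,
                   freundlich_params = freundlich_params,
                   continental_growth = continental_growth,
                   NULL)
    scenario[[parts[1L]]] <-
      if (cls[1L] == "lightning_rates")
        lightning_rates(obj$regime, nox_at_pal = obj$nox_at_pal,
                        nhx_at_pal = obj$nhx_at_pal)
      else if (is.null(ctor)) structure(obj, class = cls)
      else do.call(ctor, obj)
  }
  validate_scenario(scenario)
  scenario
}

#' Steady-state parameter sweep
#'
#' For each value on a grid, sets one scalar parameter, runs an
#' ensemble, and records the ensemble-mean end state (PAL per pool) plus
#' the volcanic degassing fluxes at the end of the run.  Parameters are
#' varied one at a time, all else held at the scenario's values.
#'
#' @param scenario an [ncycle_scenario()].
#' @param param dotted parameter path, e.g. `"degassing.alpha_m"`,
#'   `"subduction.D"`, `"erosion_rate"`, `"henry.ocean_volume"`, or
#'   `"mantle_mixing.rate"` (constant forcing); see
#'   [sweepable_params()].
#' @param values strictly monotone numeric grid.
#' @param n_members ensemble size per grid point.
#' @param seed integer base seed (shared across grid points, so members
#'   are paired).
#' @return An object of class `"ncycle_sweep"`: a data frame with one
#'   row per grid value, the end-state pools in PAL, and the end-state
#'   `arc`, `morb` and `hotspot` fluxes in kg N/yr.
#' @examples
#' \donttest{
#' sw <- ncycle_sweep(ncycle_scenario(), "degassing.alpha_m",
#'                    seq(0.1, 0.9, by = 0.2), n_members = 3, seed = 1)
#' plot(sw)
#' }
#' @export
ncycle_sweep <- function(scenario, param, values, n_members = 3, seed = 1) {
  stopifnot(inherits(scenario, "ncycle_scenario"), is.numeric(values))
  if (length(values) < 1L) stop("'values' must be a non-empty grid")
  dv <- diff(values)
  if (length(values) > 1L && !(all(dv > 0) || all(dv < 0)))
    stop("'values' must be strictly monotone")
  rows <- vector("list", length(values))
  for (j in seq_along(values)) {
    scj <- set_param(scenario, param, values[j])
    e <- ncycle_ensemble(scj, n_members = n_members, seed = seed)
    fin <- Reduce(`+`, lapply(e$members, function(m)
      m$states[nrow(m$states), ])) / n_members
    deg <- degassing_fluxes(fin[["uma_nhx"]], fin[["lma_nhx"]], scj$degassing)
    rows[[j]] <- c(value = values[j],
                   to_pal(fin, scj$henry$pal_mass), deg)
  }
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "param") <- param
  attr(out, "n_members") <- n_members
  attr(out, "seed") <- seed
  class(out) <- c("ncycle_sweep", "data.frame")
  out
}

#' @export
print.ncycle_sweep <- function(x, ...) {
  cat("nitrocycle steady-state sweep over ", attr(x, "param"),
      " (ensemble n = ", attr(x, "n_members"), ")\n", sep = "")
  print.data.frame(signif(as.data.frame(x), 4), row.names = FALSE)
  invisible(x)
}

#' Plot a sweep
#'
#' End-state atmospheric N2 (PAL) against the swept parameter.
#'
#' @param x an `ncycle_sweep`.
#' @param pool pool to display, default `"atm_n2"`.
#' @param ... passed to [plot()].
#' @export
plot.ncycle_sweep <- function(x, pool = "atm_n2", ...) {
  plot(x$value, x[[pool]], type = "b", xlab = attr(x, "param"),
       ylab = paste(pool, "(PAL)"), ...)
  invisible(x)
}

#' @export
print.ncycle_ensemble <- function(x, ...) {
  cat("nitrocycle ensemble (preset: ", x$scenario$preset, ", n = ",
      length(x$members), ")\n", sep = "")
  ct <- collapse_time(x, "atm_n2", 0.05)
  cat(sprintf("  atm_n2 collapse time (5%% spread): %s\n",
              if (is.finite(ct)) sprintf("%.0f Ma", ct / 1e6) else "never"))
  cat("  ensemble-mean final state (PAL):\n")
  fin <- Reduce(`+`, lapply(x$members, function(m)
    m$states[nrow(m$states), ])) / length(x$members)
  print(round(to_pal(fin, x$scenario$henry$pal_mass), 4))
  invisible(x)
}

#' Plot an ensemble
#'
#' Member trajectories of one pool (PAL) against time.
#'
#' @param x an `ncycle_ensemble`.
#' @param pool pool name, default `"atm_n2"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ncycle_ensemble <- function(x, pool = "atm_n2", ...) {
  m <- t(ensemble_pool_matrix(x, pool))
  matplot(x$times / 1e9, to_pal(m, x$scenario$henry$pal_mass), type = "l",
          lty = 1, col = seq_len(ncol(m)),
          xlab = "model time (Gyr)", ylab = paste(pool, "(PAL)"), ...)
  invisible(x)
}
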