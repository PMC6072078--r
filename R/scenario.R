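#' Build a simulation scenario
#'
#' A scenario bundles every model parameter: the four decay forcings
#' (cometary delivery, impact fixation, hydrothermal circulation, mantle
#' mixing), the flux-law parameter groups, the continental growth model,
#' the bulk nitrogen budget, and the integrator settings.  Scenarios
#' start from a named preset (see [ncycle_presets()]) and any field can
#' be overridden through `...`.
#'
#' @param preset name of a preset, default `"table3_high_fixation"`.
#' @param ... named overrides of top-level scenario fields: `comet`,
#'   `impact`, `hydrothermal`, `mantle_mixing` ([decay_forcing()]s),
#'   `lightning`, `degassing`, `subduction`, `henry`, `freundlich`,
#'   `growth` (parameter objects), and the scalars `erosion_rate` (m/yr),
#'   `alpha_a`, `bulk_n` (kg), `rock_uma`, `rock_lma` (kg),
#'   `ocean_volume_change_pct` (percent change since formation; negative
#'   means shrinking oceans), `dt` (yr), `t_end` (yr), `stride` (output
#'   sampling interval in steps).
#' @return An object of class `"ncycle_scenario"`.
#' @examples
#' sc <- ncycle_scenario()                      # high abiotic fixation
#' lo <- ncycle_scenario("table3_low_fixation") # N2-dominated atmosphere
#' fast <- ncycle_scenario(subduction = subduction_params(D = 5e7))
#' @export
ncycle_scenario <- function(preset = "table3_high_fixation", ...) {
  sc <- preset_scenario(preset)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(sc))
    if (length(bad))
      stop("unknown scenario field(s): ", paste(bad, collapse = ", "),
           "\n  known fields: ", paste(setdiff(names(sc), "preset"), collapse = ", "))
    sc[names(dots)] <- dots
  }
  sc <- structure(sc, class = "ncycle_scenario")
  validate_scenario(sc)
  sc
}

# Default (Table-3-style, high abiotic fixation) parameterization; all
# presets are deltas against this.
base_scenario <- function() {
  list(
    preset        = "table3_high_fixation",
    comet         = decay_forcing(F1 = 2.4e8, F0 = 2.4e5, tau = 1.5e8),
    impact        = decay_forcing(F1 = 4.7e9, F0 = 4.7e6, tau = 1.5e8),
    hydrothermal  = decay_forcing(F1 = 3e-7,  F0 = 1e-7,  tau = 1.5e8),
    mantle_mixing = decay_forcing(F1 = 3e-8,  F0 = 1e-8,  tau = 1e9),
    lightning     = lightning_rates("high"),
    degassing     = degassing_params(),
    subduction    = subduction_params(),
    henry         = henry_params(),
    freundlich    = freundlich_params(),
    growth        = continental_growth(),
    erosion_rate  = 5e-4,
    alpha_a       = 0.2,
    bulk_n        = 3.4e19,
    rock_uma      = 4e24 / 3,
    rock_lma      = 8e24 / 3,
    ocean_volume_change_pct = 0,
    dt            = 5000,
    t_end         = 4.5e9,
    stride        = 100L
  )
}

preset_table <- function() {
  list(
    table3_high_fixation = list(
      desc = "Table-3 defaults, CO2-dominated (high) abiotic fixation",
      delta = list()),
    table3_low_fixation = list(
      desc = "Table-3 defaults, N2-dominated (low) abiotic fixation",
      delta = list(lightning = lightning_rates("low"))),
    low_budget = list(
      desc = "High fixation with a low bulk silicate N budget (9.3e18 kg)",
      delta = list(bulk_n = 9.3e18)),
    subduction_50Ma = list(
      desc = "High fixation, oceanic crust turnover in 50 Ma",
      delta = list(subduction = subduction_params(D = 5e7))),
    subduction_100Ma = list(
      desc = "High fixation, oceanic crust turnover in 100 Ma (default)",
      delta = list(subduction = subduction_params(D = 1e8))),
    subduction_150Ma = list(
      desc = "High fixation, oceanic crust turnover in 150 Ma",
      delta = list(subduction = subduction_params(D = 1.5e8))),
    ocean_volume_minus50 = list(
      desc = "High fixation, ocean volume shrinking 50% since formation",
      delta = list(ocean_volume_change_pct = -50)),
    ocean_volume_plus50 = list(
      desc = "High fixation, ocean volume growing 50% since formation",
      delta = list(ocean_volume_change_pct = 50)),
    constant_forcings = list(
      desc = "High fixation with constant (present-day) hydrothermal and mixing rates",
      delta = list(hydrothermal  = decay_forcing(1e-7, 1e-7, 1.5e8),
                   mantle_mixing = decay_forcing(1e-8, 1e-8, 1e9)))
  )
}

preset_scenario <- function(name) {
  tab <- preset_table()
  if (!is.character(name) || length(name) != 1L || !name %in% names(tab))
    stop("unknown preset '", name, "'; available presets: ",
         paste(names(tab), collapse = ", "))
  sc <- base_scenario()
  sc[names(tab[[name]]$delta)] <- tab[[name]]$delta
  sc$preset <- name
  sc
}

#' List the named scenario presets
#'
#' @return A data frame with columns `preset` and `description`.
#' @export
ncycle_presets <- function() {
  tab <- preset_table()
  data.frame(preset = names(tab),
             description = vapply(tab, `[[`, "", "desc"),
             row.names = NULL, stringsAsFactors = FALSE)
}

check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop("invalid scenario field '", field, "': ", msg,
                        call. = FALSE)
}

validate_scenario <- function(sc) {
  check_that(inherits(sc$comet, "decay_forcing"), "comet", "must be a decay_forcing")
  check_that(inherits(sc$impact, "decay_forcing"), "impact", "must be a decay_forcing")
  check_that(inherits(sc$hydrothermal, "decay_forcing"), "hydrothermal", "must be a decay_forcing")
  check_that(inherits(sc$mantle_mixing, "decay_forcing"), "mantle_mixing", "must be a decay_forcing")
  check_that(inherits(sc$lightning, "lightning_rates"), "lightning", "must be lightning_rates")
  check_that(inherits(sc$degassing, "degassing_params"), "degassing", "must be degassing_params")
  check_that(inherits(sc$subduction, "subduction_params"), "subduction", "must be subduction_params")
  check_that(inherits(sc$henry, "henry_params"), "henry", "must be henry_params")
  check_that(inherits(sc$freundlich, "freundlich_params"), "freundlich", "must be freundlich_params")
  check_that(inherits(sc$growth, "continental_growth"), "growth", "must be a continental_growth model")
  check_that(is.numeric(sc$erosion_rate) && sc$erosion_rate >= 0,
             "erosion_rate", "must be a non-negative rate in m/yr")
  check_that(is.numeric(sc$alpha_a) && sc$alpha_a >= 0 && sc$alpha_a <= 1,
             "alpha_a", "must lie in [0, 1]")
  check_that(is.numeric(sc$bulk_n) && sc$bulk_n > 0,
             "bulk_n", "must be a positive mass in kg")
  check_that(is.numeric(sc$rock_uma) && sc$rock_uma > 0, "rock_uma", "must be positive")
  check_that(is.numeric(sc$rock_lma) && sc$rock_lma > 0, "rock_lma", "must be positive")
  check_that(is.numeric(sc$ocean_volume_change_pct) && sc$ocean_volume_change_pct > -100,
             "ocean_volume_change_pct", "must be a percent change > -100")
  check_that(is.numeric(sc$dt) && sc$dt > 0, "dt", "must be a positive step in years")
  check_that(is.numeric(sc$t_end) && sc$t_end >= sc$dt, "t_end", "must be >= dt")
  check_that(is.numeric(sc$stride) && sc$stride >= 1, "stride", "must be >= 1")
  invisible(sc)
}

#' @export
print.ncycle_scenario <- function(x, ...) {
  cat("nitrocycle scenario (preset: ", x$preset, ")\n", sep = "")
  cat(sprintf("  bulk silicate N     : %.3g kg (%.2f PAL)\n",
              x$bulk_n, x$bulk_n / x$henry$pal_mass))
  cat(sprintf("  lightning (%s)    : NOx %.3g, NHx %.3g kg N/yr at 1 PAL\n",
              x$lightning$regime, x$lightning$nox_at_pal, x$lightning$nhx_at_pal))
  cat(sprintf("  alpha_m / alpha_a   : %.3g / %.3g\n",
              x$degassing$alpha_m, x$alpha_a))
  cat(sprintf("  subduction D, eps   : %.3g yr, %.3g\n",
              x$subduction$D, x$subduction$eps))
  cat(sprintf("  erosion rate        : %.3g m/yr\n", x$erosion_rate))
  cat(sprintf("  ocean volume        : %.3g L (%+g%% since formation)\n",
              x$henry$ocean_volume, x$ocean_volume_change_pct))
  cat(sprintf("  integration         : dt = %g yr to t_end = %.3g yr (stride %d)\n",
              x$dt, x$t_end, as.integer(x$stride)))
  invisible(x)
}

# Instantaneous ocean volume (litres).  ocean_volume_change_pct is the
# percent change since formation; the configured henry$ocean_volume is
# the present-day (t = 4.5 Gyr) volume.
ocean_volume_at <- function(sc, t) {
  v1 <- sc$henry$ocean_volume
  v0 <- v1 / (1 + sc$ocean_volume_change_pct / 100)
  v0 + (v1 - v0) * t / 4.5e9
}

#' Save a scenario to a YAML file
#'
#' @param sc an [ncycle_scenario()].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @seealso [load_scenario()]
#' @export
save_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "ncycle_scenario"))
  plain <- lapply(unclass(sc), function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path, precision = 15L)
  invisible(path)
}

#' Load a scenario from a YAML file or preset name
#'
#' @param path_or_preset path to a YAML scenario file (as written by
#'   [save_scenario()]) or the name of a preset.
#' @return An [ncycle_scenario()].
#' @export
load_scenario <- function(path_or_preset) {
  stopifnot(is.character(path_or_preset), length(path_or_preset) == 1L)
  if (!file.exists(path_or_preset))
    return(ncycle_scenario(path_or_preset))
  raw <- yaml::read_yaml(path_or_preset)
  sc <- base_scenario()
  sc$preset <- if (is.null(raw$preset)) "custom" else raw$preset
  sc$comet <- do.call(decay_forcing, raw$comet)
  sc$impact <- do.call(decay_forcing, raw$impact)
  sc$hydrothermal <- do.call(decay_forcing, raw$hydrothermal)
  sc$mantle_mixing <- do.call(decay_forcing, raw$mantle_mixing)
  sc$lightning <- lightning_rates(raw$lightning$regime,
                                  nox_at_pal = raw$lightning$nox_at_pal,
                                  nhx_at_pal = raw$lightning$nhx_at_pal)
  sc$degassing <- do.call(degassing_params, raw$degassing)
  sc$subduction <- do.call(subduction_params, raw$subduction)
  sc$henry <- do.call(henry_params, raw$henry)
  sc$freundlich <- do.call(freundlich_params, raw$freundlich)
  sc$growth <- do.call(continental_growth, raw$growth)
  for (f in c("erosion_rate", "alpha_a", "bulk_n", "rock_uma", "rock_lma",
              "ocean_volume_change_pct", "dt", "t_end"))
    sc[[f]] <- raw[[f]]
  sc$stride <- as.integer(raw$stride)
  sc <- structure(sc, class = "ncycle_scenario")
  validate_scenario(sc)
  sc
}
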