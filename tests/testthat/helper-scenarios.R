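# Shared fixtures: scenarios with selected process groups switched off.

off <- function(tau) decay_forcing(F1 = 0, F0 = 0, tau = tau)

# every flux law silenced (subduction cannot be removed, only slowed to
# a timescale long enough to be inert over the age of the planet)
no_flux_scenario <- function(...) {
  ncycle_scenario(
    comet = off(1.5e8), impact = off(1.5e8),
    hydrothermal = off(1.5e8), mantle_mixing = off(1e9),
    lightning = lightning_rates("high", nox_at_pal = 0, nhx_at_pal = 0),
    degassing = degassing_params(f_uma_ref = 0, f_lma_ref = 0),
    subduction = subduction_params(D = 1e300),
    erosion_rate = 0,
    ...
  )
}

lightning_only_scenario <- function(regime = "high", ...) {
  ncycle_scenario(
    comet = off(1.5e8), impact = off(1.5e8),
    hydrothermal = off(1.5e8), mantle_mixing = off(1e9),
    lightning = lightning_rates(regime),
    degassing = degassing_params(f_uma_ref = 0, f_lma_ref = 0),
    subduction = subduction_params(D = 1e300),
    erosion_rate = 0,
    ...
  )
}

# apply both instantaneous equilibria once, so that a state is a fixed
# point of further partitioning
equilibrate_state <- function(s, sc, t = 0) {
  v <- nitrocycle:::ocean_volume_at(sc, t)
  s[c("atm_n2", "oce_n2")] <- partition_n2(s[["atm_n2"]] + s[["oce_n2"]], sc$henry, v)
  s[c("oce_nhx", "sed_nhx")] <- partition_nhx(s[["oce_nhx"]] + s[["sed_nhx"]], sc$freundlich, v)
  s
}

final_state <- function(traj) traj$states[nrow(traj$states), ]

ensemble_mean_final <- function(e) {
  Reduce(`+`, lapply(e$members, final_state)) / length(e$members)
}
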