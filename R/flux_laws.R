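#' Lightning fixation rates
#'
#' Electric discharges fix atmospheric N2 into soluble NOx and NHx at a
#' constant rate per unit of atmospheric N2 (linear PAL scaling, assumed
#' pressure-independent).  The high regime corresponds to a CO2-dominated
#' atmosphere (efficient fixation), the low regime to an N2-dominated
#' one.
#'
#' @param regime `"high"` (CO2-dominated) or `"low"` (N2-dominated);
#'   selects the default rate pair.
#' @param nox_at_pal,nhx_at_pal fixation fluxes to NOx and NHx in kg N/yr
#'   at 1 PAL of atmospheric N2; override the regime defaults.
#' @return An object of class `"lightning_rates"`.
#' @examples
#' lightning_rates("high")  # 4e10 / 1.6e7 kg N/yr at 1 PAL
#' lightning_rates("low")   # 2.6e6 / 1e3  kg N/yr at 1 PAL
#' @export
lightning_rates <- function(regime = c("high", "low"),
                            nox_at_pal = NULL, nhx_at_pal = NULL) {
  regime <- match.arg(regime)
  defaults <- switch(regime,
                     high = c(nox = 4e10,  nhx = 1.6e7),
                     low  = c(nox = 2.6e6, nhx = 1e3))
  nox <- if (is.null(nox_at_pal)) defaults[["nox"]] else nox_at_pal
  nhx <- if (is.null(nhx_at_pal)) defaults[["nhx"]] else nhx_at_pal
  if (nox < 0 || nhx < 0) stop("lightning rates must be non-negative")
  structure(list(regime = regime, nox_at_pal = nox, nhx_at_pal = nhx),
            class = "lightning_rates")
}

#' Volcanic degassing parameters
#'
#' Mantle nitrogen returns to the surface through volcanism, linearly
#' scaled to the nitrogen content of the source box relative to a
#' reference: the upper-mantle flux is
#' `f_uma_ref * m_uma / m_uma_ref`, split by the mantle redox parameter
#' `alpha_m` into arc-type degassing (N2, to the atmosphere) and
#' MORB-type degassing (NHx, rains out instantaneously into the ocean);
#' the lower mantle degasses `f_lma_ref * m_lma / m_lma_ref` entirely as
#' NHx through hotspot volcanism.
#'
#' The default reference pair encodes an upper-mantle volcanic processing
#' rate constant of 6.9e-8/yr, calibrated against the reference abiotic
#' steady state (arc return balancing atmospheric fixation; see the
#' methods vignette); the hotspot constant follows from the 2.5:25
#' km^3/yr hotspot:upper-mantle magma volume ratio.  Both are
#' configurable, e.g. to the much slower normalization implied by
#' modern-Earth degassing estimates (7.84-42e7 kg N/yr against 2.8e19 kg
#' of mantle N), under which the mantle becomes an effective one-way sink
#' on Gyr timescales.
#'
#' @param alpha_m arc (N2) fraction of upper-mantle degassing, in 0..1;
#'   0.19 for the present mantle, default 0.2.
#' @param f_uma_ref total upper-mantle degassing at the reference
#'   upper-mantle N mass, kg N/yr.
#' @param f_lma_ref hotspot degassing at the reference lower-mantle N
#'   mass, kg N/yr.
#' @param m_uma_ref,m_lma_ref reference mantle N masses, kg (present
#'   mantle inventory 2.8e19 kg split 1:2 upper:lower by rock mass).
#' @return An object of class `"degassing_params"`.
#' @export
degassing_params <- function(alpha_m = 0.2,
                             f_uma_ref = 6.44e11, f_lma_ref = 6.44e10,
                             m_uma_ref = 2.8e19 / 3,
                             m_lma_ref = 2 * 2.8e19 / 3) {
  if (alpha_m < 0 || alpha_m > 1) stop("'alpha_m' must be in [0, 1]")
  if (f_uma_ref < 0 || f_lma_ref < 0) stop("reference fluxes must be non-negative")
  if (m_uma_ref <= 0 || m_lma_ref <= 0) stop("reference masses must be positive")
  structure(list(alpha_m = alpha_m, f_uma_ref = f_uma_ref,
                 f_lma_ref = f_lma_ref, m_uma_ref = m_uma_ref,
                 m_lma_ref = m_lma_ref),
            class = "degassing_params")
}

#' Subduction parameters
#'
#' Marine-sediment nitrogen is removed on the oceanic-crust turnover
#' timescale `D`; a fraction `eps` is scraped into continental crust
#' during subduction, the remainder enters the upper mantle.
#'
#' @param D oceanic-crust turnover timescale, yr (default 100 Ma).
#' @param eps continental accretion efficiency, in 0..1.
#' @return An object of class `"subduction_params"`.
#' @export
subduction_params <- function(D = 1e8, eps = 0.05) {
  if (!is.finite(D) || D <= 0) stop("'D' must be a positive, finite timescale in years")
  if (eps < 0 || eps > 1) stop("'eps' must be in [0, 1]")
  structure(list(D = D, eps = eps), class = "subduction_params")
}

#' Cometary delivery flux
#'
#' Net input of reduced nitrogen from comets, asteroids, meteorites, and
#' interplanetary dust, delivered to the ocean NHx pool.  This is the
#' only flux that changes the total nitrogen inventory of the modelled
#' system.
#'
#' @param t model time, yr.
#' @param f a [decay_forcing()]; defaults follow the late-accretion
#'   decline (`F1 = 2.4e8`, `F0 = 2.4e5` kg N/yr, `tau = 150` Ma).
#' @return Flux in kg N/yr.
#' @export
comet_delivery <- function(t, f = decay_forcing(2.4e8, 2.4e5, 1.5e8)) {
  evaluate_forcing(f, t)
}

#' Impact-shock fixation flux
#'
#' Bolide shocks fix atmospheric N2 into soluble species that rain out
#' directly into the ocean.  The total is the decaying impactor forcing
#' linearly scaled to the atmospheric N2 content (1 PAL = `pal_mass`);
#' a fraction `alpha_a` (the atmospheric redox parameter) is delivered
#' reduced (NHx), the remainder oxidized (NOx).  The conversion is
#' mass-neutral: what the ocean gains the atmosphere loses.
#'
#' @param t model time, yr.
#' @param m_atm atmospheric N2 mass, kg N.
#' @param alpha_a fraction delivered as NHx, in 0..1.
#' @param f impact forcing, a [decay_forcing()].
#' @param pal_mass atmospheric mass at 1 PAL, kg N.
#' @return Named vector `c(nox, nhx)` of fluxes to the ocean, kg N/yr.
#' @examples
#' impact_fixation(0, 4e18, 0.2)  # 4.7e9 kg N/yr total at 1 PAL, t = 0
#' @export
impact_fixation <- function(t, m_atm, alpha_a = 0.2,
                            f = decay_forcing(4.7e9, 4.7e6, 1.5e8),
                            pal_mass = 4e18) {
  if (m_atm < 0) stop("'m_atm' must be non-negative")
  if (alpha_a < 0 || alpha_a > 1) stop("'alpha_a' must be in [0, 1]")
  total <- evaluate_forcing(f, t) * m_atm / pal_mass
  c(nox = (1 - alpha_a) * total, nhx = alpha_a * total)
}

#' Lightning fixation flux
#'
#' @param m_atm atmospheric N2 mass, kg N.
#' @param r a [lightning_rates()] object.
#' @param pal_mass atmospheric mass at 1 PAL, kg N.
#' @return Named vector `c(nox, nhx)` of fluxes to the ocean, kg N/yr;
#'   a mass-neutral atmosphere-to-ocean conversion.
#' @examples
#' lightning_fixation(4e18, lightning_rates("high"))
#' @export
lightning_fixation <- function(m_atm, r = lightning_rates("high"),
                               pal_mass = 4e18) {
  if (m_atm < 0) stop("'m_atm' must be non-negative")
  scale <- m_atm / pal_mass
  c(nox = r$nox_at_pal * scale, nhx = r$nhx_at_pal * scale)
}

#' Hydrothermal reduction fluxes
#'
#' Seawater circulating through hydrothermal vent systems reduces
#' dissolved nitrogen: all circulated NOx and 0.1% of circulated
#' dissolved N2 are converted to NHx.  `r_circ` is the fraction of the
#' ocean volume circulated per year.  Both conversions are internal to
#' the ocean, so total ocean nitrogen is unchanged.
#'
#' @param r_circ circulation rate, 1/yr, `>= 0`.
#' @param m_nox dissolved NOx mass, kg N.
#' @param m_n2_dissolved dissolved N2 mass, kg N.
#' @param n2_fraction fraction of circulated N2 reduced (default 1e-3).
#' @return Named vector `c(nox_to_nhx, n2_to_nhx)` in kg N/yr.
#' @export
hydrothermal_conversion <- function(r_circ, m_nox, m_n2_dissolved,
                                    n2_fraction = 1e-3) {
  if (r_circ < 0) stop("'r_circ' must be non-negative")
  if (m_nox < 0 || m_n2_dissolved < 0) stop("masses must be non-negative")
  c(nox_to_nhx = r_circ * m_nox,
    n2_to_nhx = r_circ * n2_fraction * m_n2_dissolved)
}

#' Subduction fluxes out of the marine-sediment pool
#'
#' @param m_sed sediment NHx mass, kg N.
#' @param p a [subduction_params()] object.
#' @return Named vector `c(to_uma, to_ccr)` in kg N/yr; the two parts sum
#'   to `m_sed / D` exactly.
#' @examples
#' subduction_fluxes(1e18, subduction_params(D = 1e8, eps = 0.05))
#' @export
subduction_fluxes <- function(m_sed, p = subduction_params()) {
  if (m_sed < 0) stop("'m_sed' must be non-negative")
  c(to_uma = (1 - p$eps) * m_sed / p$D, to_ccr = p$eps * m_sed / p$D)
}

#' Continental erosion flux
#'
#' Erosion returns crustal nitrogen to the ocean NHx pool.  Nitrogen is
#' assumed uniformly distributed in the crust, so the eroded volume
#' fraction per year (`erosion_rate * area / volume_cc`) carries the
#' proportional share of crustal N.  Zero while no crust exists.
#'
#' @param m_ccr continental-crust NHx mass, kg N.
#' @param erosion_rate vertical erosion rate, m/yr.
#' @param area continental surface area, m^2.
#' @param volume_cc continental crust volume, m^3.
#' @return Flux in kg N/yr.
#' @export
erosion_flux <- function(m_ccr, erosion_rate, area, volume_cc) {
  if (m_ccr < 0 || erosion_rate < 0 || area < 0 || volume_cc < 0)
    stop("all inputs must be non-negative")
  if (volume_cc == 0) return(0)
  m_ccr * erosion_rate * area / volume_cc
}

#' Volcanic degassing fluxes
#'
#' @param m_uma,m_lma upper/lower mantle NHx masses, kg N.
#' @param d a [degassing_params()] object.
#' @return Named vector `c(arc, morb, hotspot)` in kg N/yr: arc N2 to the
#'   atmosphere, MORB NHx and hotspot NHx to the ocean.
#' @examples
#' d <- degassing_params(alpha_m = 0.19, f_uma_ref = 2e8)
#' degassing_fluxes(d$m_uma_ref, 0, d)  # 19/81 arc/MORB split of 2e8
#' @export
degassing_fluxes <- function(m_uma, m_lma, d = degassing_params()) {
  if (m_uma < 0 || m_lma < 0) stop("mantle masses must be non-negative")
  total_uma <- d$f_uma_ref * m_uma / d$m_uma_ref
  c(arc = d$alpha_m * total_uma,
    morb = (1 - d$alpha_m) * total_uma,
    hotspot = d$f_lma_ref * m_lma / d$m_lma_ref)
}

#' Mantle mixing fluxes
#'
#' Convective exchange between the upper and lower mantle: rock mass
#' `r_mix * (rock_uma + rock_lma)` crosses the boundary per year in each
#' direction, carrying its source nitrogen concentration.  The fixed
#' point is equal N concentration per kg of rock in both boxes.
#'
#' @param m_uma,m_lma mantle NHx masses, kg N.
#' @param r_mix mixing rate, 1/yr (fraction of total mantle circulated).
#' @param rock_uma,rock_lma rock masses of the two boxes, kg, `> 0`.
#' @return Named vector `c(lma_to_uma, uma_to_lma)` in kg N/yr.
#' @export
mantle_mixing_fluxes <- function(m_uma, m_lma, r_mix,
                                 rock_uma = 4e24 / 3, rock_lma = 8e24 / 3) {
  if (r_mix < 0) stop("'r_mix' must be non-negative")
  if (rock_uma <= 0 || rock_lma <= 0) stop("rock masses must be positive")
  if (m_uma < 0 || m_lma < 0) stop("mantle masses must be non-negative")
  exchanged <- r_mix * (rock_uma + rock_lma)
  c(lma_to_uma = exchanged * m_lma / rock_lma,
    uma_to_lma = exchanged * m_uma / rock_uma)
}

#' Metamorphic N2 return flux (standalone diagnostic)
#'
#' Order-of-magnitude estimate of N2 returned to the atmosphere by
#' crustal metamorphism, assuming a fraction of crustal nitrogen is
#' releasable over a characteristic metamorphic timescale.  This flux is
#' a diagnostic only and is not wired into the default flux network.
#'
#' @param m_ccr continental-crust N mass, kg.
#' @param releasable_fraction fraction releasable by metamorphism (0..1),
#'   default 0.75.
#' @param timescale characteristic metamorphic age, yr, default 1e9.
#' @return Flux in kg N/yr.
#' @examples
#' metamorphic_flux_estimate(1.7e18)  # ~1.3e9 kg N/yr, order 1e9
#' @export
metamorphic_flux_estimate <- function(m_ccr, releasable_fraction = 0.75,
                                      timescale = 1e9) {
  if (releasable_fraction < 0 || releasable_fraction > 1)
    stop("'releasable_fraction' must be in [0, 1]")
  if (timescale <= 0) stop("'timescale' must be positive")
  if (m_ccr < 0) stop("'m_ccr' must be non-negative")
  releasable_fraction * m_ccr / timescale
}

#' All inter-reservoir fluxes at a given state and time
#'
#' Evaluates every directed edge of the flux network (before any flux
#' limiting) and returns them as a tidy audit record.
#'
#' @param state a [reservoir_state()] (named vector, kg N).
#' @param scenario an [ncycle_scenario()].
#' @param t model time, yr.
#' @return A data frame with columns `edge`, `from`, `to`, `species`, and
#'   `flux` (kg N/yr), one row per edge of the network.
#' @export
flux_vector <- function(state, scenario, t) {
  stopifnot(inherits(scenario, "ncycle_scenario"))
  state <- reservoir_state(state)
  p <- scenario
  imp <- impact_fixation(t, state[["atm_n2"]], p$alpha_a, p$impact,
                         p$henry$pal_mass)
  lig <- lightning_fixation(state[["atm_n2"]], p$lightning, p$henry$pal_mass)
  hyd <- hydrothermal_conversion(evaluate_forcing(p$hydrothermal, t),
                                 state[["oce_nox"]], state[["oce_n2"]])
  sub <- subduction_fluxes(state[["sed_nhx"]], p$subduction)
  vol_m3 <- continental_volume(p$growth, t) * 1e9
  ero <- erosion_flux(state[["ccr_nhx"]], p$erosion_rate,
                      continental_area(p$growth, t), vol_m3)
  deg <- degassing_fluxes(state[["uma_nhx"]], state[["lma_nhx"]], p$degassing)
  mix <- mantle_mixing_fluxes(state[["uma_nhx"]], state[["lma_nhx"]],
                              evaluate_forcing(p$mantle_mixing, t),
                              p$rock_uma, p$rock_lma)
  out <- NCYCLE_EDGES
  out$flux <- c(comet_delivery(t, p$comet),
                imp[["nox"]], imp[["nhx"]], lig[["nox"]], lig[["nhx"]],
                hyd[["nox_to_nhx"]], hyd[["n2_to_nhx"]],
                sub[["to_uma"]], sub[["to_ccr"]], ero,
                deg[["arc"]], deg[["morb"]], deg[["hotspot"]],
                mix[["lma_to_uma"]], mix[["uma_to_lma"]])
  out
}
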