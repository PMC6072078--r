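#' Henry's-law parameters for air-sea N2 partitioning
#'
#' At equilibrium the N2 partial pressure and its dissolved concentration
#' satisfy \eqn{K = p / c}.  Partial pressure is anchored to the modern
#' point: \eqn{p = p_{ref} (m_{atm} / m_{PAL})}, with 1 PAL = `pal_mass`
#' kg N in the atmosphere exerting `p_ref` atm.  Background-gas effects on
#' total pressure are ignored.  The default volatility 1600 L atm/mol is
#' the 25 degC value; it varies by about a factor of 4 between 0 and
#' 100 degC, so `K` is configurable.
#'
#' @param K Henry volatility for N2, L atm/mol, `> 0`.
#' @param ocean_volume ocean volume in litres, `> 0`.
#' @param pal_mass atmospheric N2 mass at 1 PAL, kg N (4e18).
#' @param p_ref N2 partial pressure at 1 PAL, atm (0.78).
#' @param molar_mass_n2,molar_mass_n molar masses, g/mol.
#' @return An object of class `"henry_params"`.
#' @export
henry_params <- function(K = 1600, ocean_volume = 1.37e21, pal_mass = 4e18,
                         p_ref = 0.78, molar_mass_n2 = 28, molar_mass_n = 14) {
  if (K <= 0) stop("Henry volatility 'K' must be positive")
  if (ocean_volume <= 0) stop("'ocean_volume' must be positive")
  if (pal_mass <= 0) stop("'pal_mass' must be positive")
  if (p_ref <= 0) stop("'p_ref' must be positive")
  structure(list(K = K, ocean_volume = ocean_volume, pal_mass = pal_mass,
                 p_ref = p_ref, molar_mass_n2 = molar_mass_n2,
                 molar_mass_n = molar_mass_n),
            class = "henry_params")
}

#' Freundlich adsorption parameters for NHx on marine sediments
#'
#' Reduced nitrogen partitions between seawater and sediment following
#' the empirical isotherm \eqn{Q_e = K_f C_e^{1/n}}, with \eqn{Q_e} the
#' adsorbed load per gram of sediment (mol/g) and \eqn{C_e} the dissolved
#' concentration (mol N/L here).  `sediment_solid_mass` is the mass of
#' adsorbing solid; its default is calibrated so that with the default
#' `Kf` and ocean volume the adsorbed:dissolved mass ratio is about 0.80,
#' the value the reference abiotic mass balance implies for the
#' sediment:ocean-NHx split (see the methods vignette).
#'
#' @param Kf adsorption capacity, L/g, `>= 0`.
#' @param n Freundlich exponent, dimensionless, `> 0`; `n = 1` gives a
#'   linear isotherm with a closed-form split.
#' @param sediment_solid_mass adsorbing sediment mass in grams, `>= 0`.
#' @return An object of class `"freundlich_params"`.
#' @export
freundlich_params <- function(Kf = 1e-3, n = 1, sediment_solid_mass = 1.09e24) {
  if (Kf < 0) stop("'Kf' must be non-negative")
  if (n <= 0) stop("Freundlich exponent 'n' must be positive")
  if (sediment_solid_mass < 0) stop("'sediment_solid_mass' must be non-negative")
  structure(list(Kf = Kf, n = n, sediment_solid_mass = sediment_solid_mass),
            class = "freundlich_params")
}

# dissolved:atmosphere mass ratio implied by Henry's law; linear in none
# of the masses, so the split below is exact.
henry_ratio <- function(hp, ocean_volume = hp$ocean_volume) {
  hp$p_ref * hp$molar_mass_n2 * ocean_volume / (hp$pal_mass * hp$K * 1000)
}

#' Partition total N2 between atmosphere and ocean (Henry's law)
#'
#' Splits a combined N2 inventory into atmospheric and dissolved parts so
#' that \eqn{p = K c} holds exactly.  Both relations are linear in mass,
#' so the split is closed form and conserves mass to machine precision.
#'
#' @param total_n2 combined atmospheric + dissolved N2, kg N, `>= 0`.
#' @param hp a [henry_params()] object.
#' @param ocean_volume optional instantaneous ocean volume in litres
#'   (defaults to `hp$ocean_volume`); scenarios with evolving oceans pass
#'   the current volume.
#' @return Named numeric vector `c(atm_n2, oce_n2)` in kg N, summing to
#'   `total_n2` exactly.
#' @examples
#' hp <- henry_params()
#' partition_n2(4e18, hp)   # dissolved fraction ~ 4.7e-3
#' @export
partition_n2 <- function(total_n2, hp, ocean_volume = hp$ocean_volume) {
  stopifnot(inherits(hp, "henry_params"), is.numeric(total_n2),
            length(total_n2) == 1L)
  if (total_n2 < 0) stop("'total_n2' must be non-negative")
  r <- henry_ratio(hp, ocean_volume)
  atm <- total_n2 / (1 + r)
  c(atm_n2 = atm, oce_n2 = total_n2 - atm)
}

#' Partition mobile NHx between seawater and sediment (Freundlich)
#'
#' Splits the mobile reduced-nitrogen inventory (dissolved + adsorbed)
#' so that the adsorbed load satisfies the Freundlich isotherm at the
#' dissolved concentration.  For `n = 1` the split is closed form
#' (adsorbed/dissolved = `Kf * sediment_solid_mass / ocean_volume`); for
#' `n != 1` the monotone mass-balance equation is solved by bracketed
#' root-finding to a relative tolerance of 1e-12.
#'
#' @param mobile_nhx dissolved + adsorbed NHx, kg N, `>= 0`.
#' @param fp a [freundlich_params()] object.
#' @param ocean_volume ocean volume in litres.
#' @param method `"auto"` uses the closed form when `n = 1`; `"root"`
#'   forces the generic root-finder (used to cross-check the closed form).
#' @return Named numeric vector `c(oce_nhx, sed_nhx)` in kg N, summing to
#'   `mobile_nhx` exactly.
#' @examples
#' fp <- freundlich_params()
#' partition_nhx(1e19, fp, ocean_volume = 1.37e21)
#' @export
partition_nhx <- function(mobile_nhx, fp, ocean_volume,
                          method = c("auto", "root")) {
  stopifnot(inherits(fp, "freundlich_params"), is.numeric(mobile_nhx),
            length(mobile_nhx) == 1L)
  method <- match.arg(method)
  if (mobile_nhx < 0) stop("'mobile_nhx' must be non-negative")
  if (ocean_volume <= 0) stop("'ocean_volume' must be positive")
  if (mobile_nhx == 0 || fp$Kf == 0 || fp$sediment_solid_mass == 0)
    return(c(oce_nhx = mobile_nhx, sed_nhx = 0))
  if (fp$n == 1 && method == "auto") {
    ratio <- fp$Kf * fp$sediment_solid_mass / ocean_volume
    dis <- mobile_nhx / (1 + ratio)
  } else {
    # residual of mass balance: dissolved + adsorbed(dissolved) - mobile
    # with C_e in mol N / L and Q_e in mol N / g
    conc  <- 1000 / 14 / ocean_volume        # kg N -> mol N / L
    amass <- fp$sediment_solid_mass * 14 / 1000  # mol N / g -> kg N
    g <- function(d) d + amass * fp$Kf * (d * conc)^(1 / fp$n) - mobile_nhx
    sol <- uniroot(g, lower = 0, upper = mobile_nhx,
                   f.lower = -mobile_nhx,
                   tol = mobile_nhx * 1e-13, maxiter = 2000L)
    dis <- sol$root
    if (abs(g(dis)) > mobile_nhx * 1e-9)
      stop("Freundlich root-finder failed to converge (residual = ",
           g(dis), " on mobile mass ", mobile_nhx, ")")
  }
  c(oce_nhx = dis, sed_nhx = mobile_nhx - dis)
}
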