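# nitrocycle

A kinetic box model of the global nitrogen cycle on an abiotic,
Earth-like planet, integrated from planetary differentiation to the
present (0 to 4.5 Gyr).

On a lifeless world nitrogen still moves: lightning and impact shocks
fix atmospheric N2 into soluble NOx/NHx that rains into the ocean,
hydrothermal vents reduce it, reduced nitrogen adsorbs onto marine
sediments, subduction carries it into the mantle or scrapes it onto the
continents, erosion returns it, and volcanism degasses it again.
**nitrocycle** tracks eight pools of nitrogen (kg N by reservoir and
redox class — atmosphere N2; ocean N2, NOx, NHx; sediment, crust, and
upper/lower-mantle NHx) through this flux network and asks where a
planet's nitrogen inventory ends up without biology — the baseline
against which atmospheric N2 can be read as a geo- or biosignature.
It is written for planetary scientists and astrobiologists who want a
fast, reproducible forward model with ensemble, mass-balance, and
parameter-sweep machinery.

## The model in brief

Each pool `M_i` obeys `dM_i/dt = sum(F_in) - sum(F_out)` with fluxes in
kg N/yr:

* decaying forcings `F(t) = F0 + (F1 - F0) e^(-t/tau)` for cometary
  delivery, impact fixation, hydrothermal circulation, and mantle
  mixing;
* fixation fluxes linearly scaled to atmospheric N2 in PAL
  (1 PAL = 4e18 kg N), e.g. lightning at 4e10 (NOx) + 1.6e7 (NHx)
  kg N/yr per PAL in a CO2-dominated atmosphere;
* subduction `F = M_sed/D` split by accretion efficiency `eps`;
  erosion proportional to continental area; degassing linear in mantle
  N, split by the mantle redox parameter `alpha_m` into arc N2 and
  MORB/hotspot NHx;
* two instantaneous equilibria re-imposed each step: Henry's law
  `K = p/c` for air-sea N2, and a Freundlich isotherm
  `Q_e = Kf C_e^(1/n)` for NHx adsorption on sediments.

Integration is explicit Euler at the 5000-yr step with per-pool flux
limiting, in compiled code (~0.1 s per 4.5-Gyr run). The methods
vignette (`vignettes/abiotic-nitrogen-cycle.Rmd`) derives the
calibrated constants and records every numerical choice.

## Worked example

```r
library(nitrocycle)

sc <- ncycle_scenario("table3_high_fixation")
traj <- ncycle_run(sc, seed = 1)
summary(traj)
```

```
nitrocycle trajectory summary (preset: table3_high_fixation)
          atm_n2 oce_n2 oce_nox oce_nhx sed_nhx ccr_nhx uma_nhx lma_nhx
initial   0.8766 1.3716  0.1691  0.1623  0.5062  3.3604  1.4273  0.6265
time mean 0.5569 0.0027  0.0523  3.7283  2.9663  0.1763  0.3794  0.6467
final     0.5286 0.0025  0.0529  3.7846  3.0111  0.1204  0.3833  0.6259
total N: 3.4e+19 -> 3.404e+19 kg (conservation audit 1.76e-08)
```

All values are in PAL. From an arbitrary random initial distribution
(8.5 PAL of bulk silicate nitrogen), the high-fixation planet settles
onto a state with most nitrogen in the ocean as NHx (3.78 PAL) and
adsorbed on sediments (3.01 PAL), an atmosphere thinner than today's
(0.53 PAL), and about 1 PAL left in the mantle. Total nitrogen grows
only by the cometary input, and the audit confirms the budget closes
to ~1e-8.

The ensemble statistics behind those numbers:

```r
e <- ncycle_ensemble(sc, n_members = 10, seed = 1)
round(average_balance(e, window = c(4.0e9, 4.5e9)), 2)
#>  atm_n2  oce_n2 oce_nox oce_nhx sed_nhx ccr_nhx uma_nhx lma_nhx
#>    0.53    0.00    0.05    3.78    3.01    0.12    0.38    0.63
collapse_time(e, "atm_n2", tol = 0.05) / 1e6
#> [1] 437.5   # Ma: members forget their initial conditions in < 500 Ma
```

Switching to `"table3_low_fixation"` (an N2-dominated atmosphere with
~4 orders of magnitude weaker lightning fixation) inverts the picture:
the atmosphere becomes the dominant pool at ~8 PAL, and ensembles take
several Gyr to collapse.

Parameter sweeps map the steady state, e.g.
`ncycle_sweep(sc, "degassing.alpha_m", seq(0.1, 0.9, 0.2))` shows
atmospheric N2 rising with mantle oxidation. A command-line interface
(`inst/cli/ncycle`) exposes `run`, `ensemble`, `sweep`, and `presets`
with CSV + JSON-manifest output.

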