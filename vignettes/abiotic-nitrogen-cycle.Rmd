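---
title: "Modelling a global abiotic nitrogen cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a global abiotic nitrogen cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrocycle)
```

## The question

Molecular nitrogen dominates Earth's modern atmosphere, but on a
lifeless planet with Earth-like geodynamics nothing biological pulls N2
out of the air or pumps fixed nitrogen back. **nitrocycle** asks where
the planetary nitrogen inventory ends up when only abiotic processes
operate over the 4.5 Gyr from planetary differentiation to the present:
how much stays aloft, how much dissolves, adsorbs, subducts, and
degasses again. The answer matters for interpreting atmospheric N2 as a
remote geo- or biosignature: an atmosphere holding far less (or far
more) nitrogen than its expected bulk inventory says something about
the planet's interior cycling even before biology enters the picture.

## Model structure

The model is a kinetic mass-flux box network. Eight pools, each a mass
of nitrogen atoms in kg N, represent reservoir x species combinations:

| pool      | reservoir          | species |
|-----------|--------------------|---------|
| `atm_n2`  | atmosphere         | N2      |
| `oce_n2`  | ocean, dissolved   | N2      |
| `oce_nox` | ocean, dissolved   | NOx     |
| `oce_nhx` | ocean, dissolved   | NHx     |
| `sed_nhx` | marine sediments   | NHx (adsorbed) |
| `ccr_nhx` | continental crust  | NHx     |
| `uma_nhx` | upper mantle       | NHx     |
| `lma_nhx` | lower mantle       | NHx     |

NHx and NOx are lumped redox classes (ammonia-like and
nitrite/nitrate-like); individual compounds are not resolved. The ocean
is the only reservoir hosting all three classes, which makes it the
switchboard of the network. Masses are reported in PAL, with
1 PAL = 4e18 kg N, the modern atmospheric N2 inventory.

### Time-dependent forcings

Four rates decay from a vigorous early-planet value to a modern value
with the two-level exponential `F(t) = F0 + (F1 - F0) exp(-t/tau)`
([decay_forcing()]); model time starts at planet formation:

| forcing                  | F1      | F0      | tau    | units    |
|--------------------------|---------|---------|--------|----------|
| cometary delivery        | 2.4e8   | 2.4e5   | 150 Ma | kg N/yr  |
| impact fixation (1 PAL)  | 4.7e9   | 4.7e6   | 150 Ma | kg N/yr  |
| hydrothermal circulation | 3e-7    | 1e-7    | 150 Ma | 1/yr     |
| mantle mixing            | 3e-8    | 1e-8    | 1 Gyr  | 1/yr     |

One published parameter table lists the hydrothermal row with the
cometary `F0`/`F1` values in kg N/yr, which is dimensionally
inconsistent with a circulation rate; the dimensionless rates above are
used and that row is treated as an erratum. Singular events (e.g. a
Moon-forming impact) and stochastic forcing are deliberately excluded.

### Flux laws

All fluxes are in kg N/yr and, except for the constant external comet
term, are homogeneous of degree one in their source mass — a property
the test suite checks and which guarantees that no source-proportional
law can drive a pool negative in the continuum limit.

* **Cometary delivery** adds reduced nitrogen directly to `oce_nhx`.
  It is the only flux that changes the total inventory, which is what
  the conservation audit exploits.
* **Impact fixation** converts `atm_n2` into dissolved species at the
  impact forcing scaled by `m_atm / 4e18` (half the flux at 0.5 PAL).
  A fraction `alpha_a` (atmospheric redox parameter, default 0.2)
  arrives as NHx, the rest as NOx. The published description says only
  that shock-fixed nitrogen "can be reduced or oxidized"; reading
  `alpha_a` as the reduced fraction is this package's interpretation,
  and rainout is treated as instantaneous, so fixed nitrogen lands in
  the ocean within one step.
* **Lightning fixation** converts `atm_n2` at constant per-PAL rates:
  4e10 (NOx) and 1.6e7 (NHx) kg N/yr in the CO2-dominated (high) regime,
  2.6e6 and 1e3 kg N/yr in the N2-dominated (low) regime.
* **Hydrothermal conversion** reduces all circulated NOx and 0.1% of
  circulated dissolved N2 to NHx, at the circulation-rate forcing.
* **Subduction** removes sediment N on the crust-turnover timescale
  `D` (default 100 Ma); a fraction `eps` (default 0.05) accretes to
  continental crust, the rest enters the upper mantle as NHx.
* **Erosion** returns crustal N to the ocean in proportion to the
  eroded volume fraction, `rate * area / volume`. With a fixed mean
  crustal thickness this is `rate / thickness` per year once crust
  exists.
* **Degassing** scales with mantle N content: the upper-mantle flux
  splits `alpha_m` (default 0.2) to arc volcanism (N2, to the
  atmosphere) and `1 - alpha_m` to MORB volcanism (NHx, raining out
  into the ocean); the lower mantle degasses entirely as hotspot NHx.
* **Mantle mixing** exchanges rock mass `r_mix * (rock_u + rock_l)`
  per year in both directions, each parcel carrying its source
  concentration; its fixed point is equal concentration per kg rock.

### Instantaneous equilibria

Fixed species have atmospheric residence times of days and the ocean
mixes in ~1600 yr, both far below the 5000-yr step, so two partitions
are re-imposed after every step rather than integrated:

* **Henry's law** (`K = p/c`, `K` = 1600 L atm/mol at 25 degC) splits
  total N2 between `atm_n2` and `oce_n2`. With partial pressure
  anchored at 0.78 atm per PAL, the dissolved:atmospheric ratio is
  `p_ref * M_N2 * V / (pal * K * 1000)` = 4.7e-3 — about 1.9e16 kg
  dissolved under a modern-like atmosphere, the observed order of
  magnitude.
* **A Freundlich isotherm** (`Q_e = Kf * C_e^(1/n)`, `Kf` = 1e-3 L/g,
  `n` = 1) splits mobile NHx between seawater and sediments. For
  `n = 1` the split is closed-form; otherwise the monotone mass
  balance is solved by bracketed root-finding to 1e-12 relative and
  cross-checked in the tests against a brute-force grid scan.

Both partitions conserve mass to machine precision and are idempotent,
which the suite asserts directly.

## Calibrated constants

Three constants are not pinned down by any published value and are
documented here as this package's calibration choices. They are
ordinary configurable parameters; none is touched by the test suite at
run time.

**Sediment solid mass (1.09e24 g).** The isotherm needs the mass of
adsorbing solid, for which no value is published, and the published
unit convention (C_e in mM, Q_e in mol/g) cannot reproduce the quoted
reservoir sizes with any realistic sediment mass. The package works in
mol N/L and chooses the solid mass so that the adsorbed:dissolved
ratio `Kf * S / V` is 0.796, the sediment:ocean-NHx ratio of the
reference high-fixation mass balance (3.05/3.82 in PAL).

**Degassing rate constants (6.9e-8/yr upper mantle, 3.45e-9/yr lower
mantle).** Degassing is linear in mantle N: `f_ref * m / m_ref`, so
only the ratio `k = f_ref/m_ref` matters. Normalizing with
modern-Earth estimates (7.84-42e7 kg N/yr against 2.8e19 kg of mantle
N) gives k ~ 1e-11/yr, a ~100-Gyr mantle residence time. Under that
normalization the mantle is a one-way sink: with sediments holding a
few PAL, subduction injects ~1e11 kg N/yr that volcanism cannot
return, and the entire inventory ends up in the mantle — contradicting
the reference steady state this model family reports (mantle pools
below 1 PAL, oceans near 7 PAL). The reference distribution itself
pins the constant: in steady state arc degassing must balance
atmospheric fixation, `alpha_m * k_u * m_uma = 4.0e10 * a` with
a = 0.50 PAL of atmospheric N2 and 0.36 PAL in the upper mantle, giving
`k_u = 6.9e-8`/yr (a ~15-Myr processing time for the upper-mantle
melting zone). The hotspot constant follows from the 2.5:25 km^3/yr
hotspot:upper-mantle magma volume ratio and the 1:2 rock-mass split,
`k_l = 0.05 k_u`. Solving the full closed-form steady state with these
two constants reproduces all eight reference pools to ~10%, which is
the package's justification for the defaults; the slow "modern flux"
normalization remains available through `degassing_params()`.

**Erosion rate (5e-4 m/yr).** Published sources give both 5e-4 m/yr
(parameter table) and a modern range of 1-5e-5 m/yr (text). The crustal
mass balance decides: with `eps * M_sed / D` entering the crust and
`m_ccr * rate / thickness` leaving it, only the 5e-4 value yields the
reference crustal pool (~0.2 PAL); at 5e-5 the crust would hold ~1 PAL.
The default is therefore 5e-4 m/yr, with the modern range available via
`erosion_rate`.

Other fixed choices: mean crustal thickness 40 km (geometry is never
published; only the ratio rate/thickness enters); continental growth
3 km^3/yr to 3 Ga then 0.8 km^3/yr (the constant-growth alternative
ramps linearly to the same 6.9e9 km^3 so scenarios are volume-matched
at present); mantle rock mass 4e24 kg split 1:2 upper:lower, with the
present 2.8e19 kg of mantle N split the same way for the degassing
references; comet-delivered nitrogen enters the ocean NHx pool (it is
described only as "reduced nitrogen"; the ocean is where every other
delivery flux lands).

## Numerical scheme

Explicit Euler with the published 5000-yr step, 900,000 steps over
4.5 Gyr, in compiled code (an R reference stepper, `ncycle_step()`, is
cross-checked against it in the tests). Within a step the order is:
evaluate all flux laws at `(state, t)`; scale any pool's outflows down
if they would overdraw it within one step (flux limiting — the safe
contract, though source-proportional laws make it a near-no-op at the
default step); update; re-impose the two equilibria. The operation
order is not externally specified; a dt-halving test (2500 vs 5000 yr
changes every end-state pool by < 1%) guards against order artifacts.
Stiff sub-processes (rainout, ocean mixing, adsorption) are exactly the
ones handled as instantaneous equilibria, so no implicit solver is
needed. A pool drained to zero can land a rounding error below zero;
values within 1e-12 of the total inventory below zero are clamped, far
under the 1e-9 relative conservation tolerance audited over a full
run. Fixation draws from `atm_n2` before Henry re-equilibration;
double-counting cannot occur because the partition is a pure
repartition of the combined N2 pool.

Trajectories are sampled every 100 steps (0.5 Myr) by default. The
conservation audit compares total N at every sample against the
closed-form integral of the cometary source; the worst relative
deviation is stored on every trajectory (~2e-8 with delivery on,
dominated by the left-endpoint quadrature of the decaying comet term;
~1e-13 with delivery off).

## Initial conditions and ensembles

Nothing constrains the nitrogen distribution at differentiation, so
initial states are drawn uniformly on the 8-simplex (symmetric
Dirichlet, concentration 1) scaled to the bulk budget (3.4e19 kg N
bulk-silicate default; 9.3e18 kg in the `low_budget` scenario). An
ensemble runs `n` such draws (member `i` seeded `seed + i`) and the
collapse time is the earliest sampled time after which the relative
spread (max - min over mean) of a pool stays below a tolerance
(default 5%; no published value exists, so this is the package's
convention). Under high fixation the atmosphere's collapse time is a
few hundred Myr; under low fixation the atmosphere exchanges nitrogen
so slowly that collapse takes several Gyr.

What the generator emulates is ignorance of initial conditions under a
fixed bulk budget. What it does not emulate: correlated initial
states from accretion models, early atmosphere-stripping impacts,
core sequestration, or any uncertainty in the flux laws themselves.
Passing ensemble tests therefore demonstrate insensitivity to initial
conditions only — not robustness to structural model error.

## Averaged balances

The reference mass-balance table this model family reports is an
"average" without a stated window. The low-fixation atmosphere is
still growing at 4.5 Gyr (its sinks are far smaller than its sources),
so a full-run average can never reach the reported 8 PAL; the values
behave instead like the tracked steady state after initial-condition
collapse. `average_balance()` therefore defaults to the full-run
time-weighted mean but the package's reference comparisons (acceptance
script and tests) use the late window 4.0-4.5 Gyr, chosen a priori
from that steady-state analysis. With the defaults the late-window
ensemble means are: high fixation — atmosphere 0.53, ocean NHx 3.78,
sediments 3.01, crust 0.12, upper/lower mantle 0.38/0.63, ocean NOx
0.05, ocean N2 0.002 PAL; low fixation — atmosphere 8.07 PAL with all
other pools below 0.2 PAL. These are the numbers the acceptance script
recomputes.

## Sensitivities

`ncycle_sweep()` varies one scalar at a time and records ensemble-mean
end states. Directions established by the steady-state structure and
verified by the suite on 5-point grids: atmospheric N2 increases with
hydrothermal circulation, mantle redox `alpha_m`, erosion rate, and
with faster subduction (smaller `D`); it decreases with mantle mixing,
accretion efficiency `eps`, and ocean volume. Whether such end states
are single-run or ensemble quantities is not specified anywhere;
ensemble means are used throughout (sweeps default to 3 members with
paired seeds across grid points, enough because the late-time state is
nearly initial-condition-free).

## Problem sizes

Every full run in the tests and the acceptance script integrates the
complete 4.5-Gyr, 900,000-step problem — the compiled core makes a run
~0.1 s, so nothing is scaled down. Ensembles use 10 members for the
balance and collapse statistics (matching the reference analysis) and
3 members per grid point in sweeps; the Dirichlet moment check uses
1e4 draws.

## Known limitations

Deliberately out of scope: aqueous ammonium-nitrite reversion of fixed
nitrogen to N2 (no usable rate law at ocean scale; its upper bounds
span ten orders of magnitude), UV/CME-driven fixation, gas-phase C-N
photochemistry, climate feedback of pN2 on temperature, ice
sequestration and atmospheric escape, nitrogen isotopes, a core
reservoir, and pH/speciation chemistry within the lumped NHx/NOx
classes. The mantle redox parameter `alpha_m` is constant in time, and
lightning rates are pressure-independent. The sediment mass and its
adsorption capacity are fixed in time, although early oceans were
likely sediment-poor. The metamorphic crust-to-atmosphere flux is
implemented only as the standalone diagnostic
`metamorphic_flux_estimate()` (order 1e9 kg N/yr on Gyr timescales)
and is not wired into the network.
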