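---
title: "Bioenergetic growth and waste simulation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bioenergetic growth and waste simulation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquafarm)
```

## The energy balance

All four species are grown by the same daily energy balance,

$$\frac{dw}{dt} = \frac{A - C}{\varepsilon},$$

where $w$ is body weight (g), $A$ the anabolic rate (J d⁻¹), $C$ the
catabolic rate (J d⁻¹) and $\varepsilon$ the energy density of body tissue
(J g⁻¹). The balance is integrated with a classical fourth-order
Runge-Kutta scheme at a fixed step of one day, matching the daily
resolution of the forcing data and of every output. What differs between
species is how $A$ and $C$ respond to the environment:

* **Finfish (gilthead seabream, European seabass).** Food is the pellet
  ration offered by the farmer. Potential ingestion scales as
  $i_{max}\,f_A(T)\,w^m$ (g feed d⁻¹) and realized ingestion is capped by
  the ration; the surplus ration is *uneaten feed*. Ingested feed is split
  into protein, lipid and carbohydrate by the (time-constant) feed
  composition; each class is digested with its own digestibility, the
  undigested remainder is egested as *faeces*, and the digested energy
  times a net anabolic efficiency $\alpha$ gives $A$. Catabolism is
  $k_C\,e^{p_C (T - T_{ref})} w^{n_C}$.
* **Mussel.** The animal is split into a somatic and a gonadic dry-weight
  compartment. A clearance rate $CR_{max} f_F(T)\, w_d^{b}$ (l d⁻¹)
  filters phytoplankton carbon (chlorophyll-a times a C:chl ratio,
  default 50) and detritus + zooplankton carbon (POC minus phytoplankton
  C, clipped at zero). Filtered carbon above an ingestion-capacity
  threshold is rejected as *pseudofaeces*; ingested carbon is absorbed
  with pool-specific efficiencies and the unabsorbed part leaves as
  *faeces*. Both egesta are converted to N and P through the POC C/P and
  N/P molar ratios. Positive net production is partitioned between soma
  and gonad once the animal is mature and the water is warm enough for
  gametogenesis; spawning (see below) empties the gonad.
* **Manila clam.** A reduced filter-feeder form: $A$ is proportional to a
  hyperbolic chlorophyll response, a Gaussian temperature response and the
  body surface ($w^{2/3}$); $C$ scales linearly on weight with an
  exponential temperature response. Its outputs are restricted to weight,
  length, metabolic rates and the temperature functions.

Two temperature-response forms cover every process: a Gaussian optimum
curve $e^{-((T-T_{opt})/\sigma)^2}$ for anabolic/filtration processes
(equal to 1 at the optimum) and a normalized exponential
$e^{p(T-T_{ref})}$ for catabolic ones (equal to 1 at the reference
temperature). Outside $[-2, 40]$ °C the package refuses to evaluate them:
these empirical forms are not trusted outside their calibration range.

Oxygen consumption converts respired energy through the oxycalorific
coefficient (13 560 J g O₂⁻¹); ammonia-N excretion is the nitrogen content
of the catabolized protein (protein fraction of catabolism × 0.16 g N per
g protein). The clam parameter set intentionally carries no such
coefficients — its formulation does not output O₂/NH₄ — and requesting
them raises a parameter error.

## Parameter sets and their provenance

Each species ships a plain-text parameter table
(`inst/extdata/params_<species>.csv`, columns
`symbol,value,units,description`) that users can copy and edit; a
workspace always carries its own editable copy. The functional forms are
fixed by the package, the constants are data. Values were chosen once from
the shellfish/finfish bioenergetics literature and adjusted in a single
calibration pass so that the default synthetic Adriatic forcings reproduce
typical Mediterranean rearing outcomes: a seabream seeded at 80 g on 1
June reaches ≈380 g by 1 May; a mussel seeded at 2.5 cm (0.0334 g dry
weight) in September passes 5 cm about seven months later and peaks at
faeces plus pseudofaeces of a few tens of mg ind⁻¹ d⁻¹; a clam seeded at
0.007 g in March approaches the 25 mm commercial length after ~15 months.
They were not revisited after that pass. Parameters that matter most:

| symbol | meaning | units |
|---|---|---|
| `eps` | energy density of body tissue | J g⁻¹ |
| `imax`, `m` | finfish maximum ingestion coefficient and exponent | g g⁻ᵐ d⁻¹, – |
| `alpha_ana` | net anabolic efficiency on digested energy | – |
| `dig_*`, `en_*` | digestibility and energy content per feed class | –, J g⁻¹ |
| `k_cat`, `n_cat`, `pc_cat`, `tref_cat` | catabolism coefficient, exponent, T-sensitivity, reference T | J g⁻ⁿ d⁻¹, –, °C⁻¹, °C |
| `crmax`, `b_cr`, `ing_cap` | mussel clearance coefficient, exponent, ingestion capacity | l d⁻¹ g⁻ᵇ, –, mg C d⁻¹ g⁻ᵇ |
| `ae_phyto`, `ae_det`, `en_food` | absorption efficiencies and food energy content | –, J mg C⁻¹ |
| `aw`, `bw` | length–weight allometry | g (cm or mm)⁻ᵇʷ, – |
| `c_to_chl` | phytoplankton carbon-to-chlorophyll ratio | g C (g chl)⁻¹ |

The carbon-to-chlorophyll ratio (default 50) and the O₂/NH₄ coefficients
are deliberately configurable: they are conversion conventions rather than
biology, and site-specific values can be supplied through the parameter
file or `species_params(..., overrides = )`.

## Forcings, interpolation and the synthetic generator

Forcing files are two-column CSVs (`date,value`, ISO dates). Records may
be unequally spaced; `interpolate_daily()` fills the simulation window by
piecewise-linear interpolation, preserving the original records exactly.
The scheme is linear by choice: anything higher-order would invent
extrema between sparse observations. There is **no extrapolation** — a
window not covered by the data is a hard error, because silently inventing
forcing values would corrupt a simulation without warning. Derived mussel
food pools are computed on the daily grid first and interpolated linearly
at the Runge-Kutta half-steps; the feed ration is held constant within
each day (zero-order hold) because it is a management decision, not a
field measurement — the winter feeding pause is simply a run of zeros in
the ration file.

`generate_synthetic_forcings()` emulates a Northern-Adriatic seasonal
cycle per variable: a sinusoid (mean, amplitude, day-of-year of the
maximum) plus Gaussian noise, clipped at zero for concentrations and
ration. Defaults: SST 16 ± 9 °C peaking in early August; chlorophyll-a
1.8 ± 1.2 µg l⁻¹ peaking in mid-April; POC 0.5 ± 0.25 mg C l⁻¹; POM
1.2 ± 0.5 mg l⁻¹; TSM 6 ± 3 mg l⁻¹; Redfield-like POC ratios (C/P 106,
N/P 16); a feed schedule that peaks in late summer and falls to ~0 at its
late-winter trough. The generator reproduces the *seasonality and
variance* of coastal forcings, not their autocorrelation, cross-variable
coherence (e.g. chlorophyll responding to riverine TSM pulses) or
satellite gaps. Tests passing on synthetic forcings therefore demonstrate
correctness of the numerics and budgets under realistic magnitudes — not
skill against field data, which the underlying model families have been
validated on separately.

## Numerical choices and degenerate inputs

* Fixed step $h = 1$ d; forcings at half-steps by linear interpolation.
  No adaptive or stiff stepping: the right-hand sides are smooth and mild.
* If an internal Runge-Kutta stage (or the updated state) goes negative it
  is clipped at zero with a warning rather than an error: the empirical
  forms can transiently undershoot near $w \to 0$ under starvation.
  Non-finite derivatives abort with the day and state in the message.
* Events are applied *between* daily steps, after the update, keeping the
  right-hand side smooth for the solver. The mussel spawning trigger —
  gonad/soma ratio above `spawn_ratio` with water warmer than `t_spawn` —
  instantaneously transfers the whole gonad out of the system and is
  logged in the trajectory's event table.
* `days_to_size()` returns the first day index whose metric meets the
  threshold; "never within the window" is the `NA` sentinel, serialized
  as an empty CSV cell and as the declared NetCDF fill value with a flag
  variable separating *not reached* from *land/failed cell*.
* Ties and thresholds: the pseudofaeces branch activates strictly above
  the ingestion capacity, so filtration exactly at capacity produces zero
  pseudofaeces.

## Population up-scaling

The farmed population is an ensemble of independent individuals. Each
ensemble member draws an initial weight and one rate trait — ingestion
rate for finfish, maximum clearance rate for the mussel, and the
food-uptake coefficient for the clam, whose formulation has no clearance
term — from normal distributions truncated at zero by redraw (the
distribution family is a documented convention; the literature states
only means ± SDs). All draws happen up front from a single seeded stream,
so results are reproducible and independent of the execution order of the
ensemble. Defaults reproduce the typical Adriatic seabream husbandry:
52 988 individuals seeded at 80 ± 8 g on 1 June, ingestion rate
0.09 ± 0.018 g g⁻ᵐ d⁻¹, natural mortality 0.00041 d⁻¹, 5000 Monte Carlo
runs, harvested 1 May.

Abundance follows $N(t) = N_0 e^{-mt}$ between husbandry events; the
default plan stocks once and harvests everything at the end. Farm-level
fluxes are the ensemble per-capita mean times $N(t)$, reported in kg d⁻¹
(kg N d⁻¹ for ammonia). Standard deviations use the sample ($n-1$)
denominator. Husbandry bookkeeping sometimes records the harvested count
as equal to the seeded count even under nonzero mortality; the result
object therefore reports both the nominal figure and the mortality-law
$N$ at harvest, without reconciling them.

## Spatial mode

`run_grid()` applies the individual model independently to every unmasked
cell of a `(time, lat, lon)` NetCDF forcing stack, producing per-cell
trajectories and days-to-commercial-size maps (mussel defaults: 5 cm, the
minimum legal size, and 7 cm, the commercial target). Cells share no
state, so grid results are identical to per-cell scalar runs and
order-invariant; cell-level failures are recorded in a status matrix
without aborting the grid. Variables absent from the file (typically TSM,
POM and POC, for which no satellite product exists) are imposed as
spatially uniform constants — a documented simplification; nothing in the
design prevents supplying them as file variables instead.

## Problem sizes used by the checks

The shipped tests and the acceptance script exercise: 365-day solver and
budget runs; full default rearing cycles per species (305–473 days);
ensembles of 4–500 simulated individuals plus trait-only draws at
n = 5000; and 2×2 to 3×3 grids over 100–380 days. These sizes were chosen
as the smallest that exercise every seasonal regime (summer growth,
winter pause, spawning) while keeping a full check run in minutes.

## Known limitations

* Parameter values are a package-level calibration to typical
  Mediterranean magnitudes, not a re-fit to any site; quantitative use at
  a specific farm requires overriding them from local data.
* Feed composition is constant over the cycle; real farms switch diets.
* No density dependence: mortality is constant and individuals do not
  interact (no food depletion inside the farm).
* The ration is per individual; converting farm feeding plans to
  per-capita rations is left to the user.
* The spatial mode assumes the native grid of the forcing file (no
  regridding) and spatially uniform imposed constants.
* Sub-daily processes (tidal resuspension, diel feeding) are below the
  model's resolution.
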