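---
title: "Methods: a spatial farm-fishery equilibrium model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a spatial farm-fishery equilibrium model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oceanfarm)
```

# Overview

`oceanfarm` simulates a single wild fish stock on a one-dimensional wrapped
lattice of $n = 100$ patches, harvested by a fishery and perturbed by the
introduction of ocean farms. Farms couple into the system three ways: they
attract wild fish (aggregation-device effect), they exclude fishing from the
patches they occupy (refuge effect, with the displaced effort redistributed),
and they alter local conditions (an elevated biomass ceiling from the
structure and feed subsidy; optionally a natural-mortality multiplier for
net fitness benefits or harms). Every farm scenario is run to equilibrium
and compared against the business-as-usual (BAU) equilibrium of the same
stock and management without farms:

$$\delta_B = \frac{B_{\text{farm}}}{B_{\text{BAU}}}, \qquad
  \delta_C = \frac{C_{\text{farm}}}{C_{\text{BAU}}}.$$

The model is deterministic throughout; there is no stochastic component
anywhere, so any run is bit-identical on repetition.

# State and annual cycle

The state is a patches $\times$ ages matrix of abundances $N_{i,a}$ (ages
$0$ to a plus group at `max_age`) together with a matching matrix of mean
individual weights $w_{i,a}$, which evolve under density-dependent growth.
One simulated year applies six stages in fixed order.

## 1. Adult movement

Baseline movement follows a wrapped Gaussian kernel. With wrapped distance
$d_{ij} = \min(|i-j|,\, n - |i-j|)$,

$$p_{ij} \propto \exp\!\left(-\frac{d_{ij}^2}{2\sigma_m^2}\right),$$

rows normalised to sum to one. The scale derives from a species "home
range" expressed as a fraction of the whole lattice:
$\sigma_m = \texttt{range\_fraction} \cdot n / 4$ (so $\pm 2\sigma_m$ spans
the range); `range_fraction = 0` is a sessile species (identity kernel).

*Density-dependent emigration.* Fish leave crowded patches and stay where
there is spare capacity. The fraction of patch $i$'s fish that disperses
through the kernel in a given year is

$$e_i = \min\!\left(1,\; \frac{b_i / K_i}{\theta}\right),$$

where $b_i$ is patch biomass, $K_i$ the patch carrying capacity, and
$\theta$ (`move_threshold`) the crowding level at which mixing is complete;
the remaining fraction $1 - e_i$ stays put. In a spatially uniform system
every patch has the same $e_i$, and a uniform distribution maps to itself
under any uniform mixing rate, so BAU equilibria are unaffected by this
mechanism. It matters exactly where farms make space heterogeneous: farm
patches carry a tripled ceiling $K$, so their relative crowding is low and
fish are retained until the farm fills, after which spillover to the
surrounding fishery resumes. Both the refuge value of farms and the
magnitude of spillover depend on $\theta$; it is a calibrated fixture
constant (default 0.75). The emigration stage can be disabled
(`step_population(dd_movement = FALSE)`) to recover plain kernel mixing.

*Attraction.* Within a farm's zone of influence (ZOI; all patches within
$\lceil 2\sigma_m \rceil$ of a farm patch by default), moves that end on a
farm patch have their unnormalised kernel weight multiplied by the
attraction strength $A \ge 1$ before row renormalisation:

$$w_{ij}^{\text{farm}} = A \, \exp\!\left(-\frac{d_{ij}^2}{2\sigma_m^2}\right),
  \qquad i \in \text{ZOI},\; j \in \text{farms}.$$

A fish inside the zone is then up to $A$ times as likely to settle the year
on a farm patch as on an equidistant plain patch. At the top of the studied
range ($A = 15$) this concentrates equilibrium farm densities by an order
of magnitude, consistent with the densities observed around real
aggregation structures. An alternative reading, flattening the Gaussian
toward farms by dividing the exponent by $A$
(`apply_attraction(form = "exponent")`), is also implemented; it was
rejected as the default because farm-bound weights are then bounded by the
self-move weight, so attainable concentration saturates within a factor of
a few regardless of $A$, which cannot produce either the strong
concentrations or the catch losses that aggregation is known to cause.

## 2. Density-dependent growth factor

Each patch's growth conditions for the year are summarised by
$g_i = \max(0,\, 1 - b_i / K_i)$ computed after movement. $K_i$ is tripled
in farm patches (`k_multiplier = 3`), representing structure and feed
subsidy raising the local biomass ceiling.

## 3. Recruitment

Larval production is proportional to mature biomass (ages
$\ge$ `age_mature`) with a fecundity coefficient; larvae enter a common
pool and settle uniformly: $s_i = \text{larvae}/n$. Settlers survive a
per-patch Beverton–Holt bottleneck

$$R_i = \frac{s_i}{1 + s_i / (h\,K^{\text{base}}_i)},$$

with steepness-like parameter $h$ (`recruit_steepness`): the asymptotic
recruitment a patch can support is $h\,K^{\text{base}}_i$. The bottleneck
saturates on the *baseline* habitat capacity, not the farm-raised ceiling:
farm structure raises the adult growth/biomass ceiling, but the nursery
capacity of the seabed beneath it is unchanged. (Letting the farm
multiplier inflate recruitment capacity turns farms into net recruitment
factories and makes catch increase monotonically with farm area, contrary
to the aggregation-loss behaviour the model is designed to capture.)

## 4. Effort

Fishing mortality in patch $i$ is $F_i \nu_a$ with logistic length
selectivity $\nu_a = 1/(1 + e^{-s(L_a - L_{\text{legal}})})$. The spatial
field of $F$ follows a gravity rule: effort is proportional to fishable
biomass (selectivity-weighted, zero in farm patches). Farm closures
therefore redistribute the displaced effort over the remaining patches,
conserving aggregate effort; with a fraction $P$ of patches farmed and a
uniform stock, every open patch's $F$ is inflated by $1/(1-P)$.

Two management regimes set the aggregate effort:

- **strong**: constant aggregate effort at the maximum-sustainable-yield
  (MSY) level of the no-farm system, found once by a coarse grid scan of
  the equilibrium yield curve refined by golden-section search
  (`find_msy_effort()`), and held fixed in all farm scenarios;
- **weak** (open access): each year the aggregate effort maximises that
  year's profit, $\text{price} \cdot C(E) - \text{cost} \cdot E$, by
  one-dimensional golden-section search with endpoint checks
  (`open_access_effort()`). The fixture price/cost ratio leaves the
  no-farm open-access equilibrium well below the MSY biomass — an
  overfished baseline.

## 5. Harvest

Natural and fishing mortality act simultaneously through a combined
exponential with Baranov catch accounting:

$$Z_{i,a} = M_i + F_i \nu_a, \qquad
  C_i = \sum_a \frac{F_i \nu_a}{Z_{i,a}} N_{i,a}
  \left(1 - e^{-Z_{i,a}}\right) w_{i,a}.$$

In farm patches $M_i = M \cdot m$, where the multiplier $m$ folds net farm
fitness effects into natural mortality ($m < 1$: supplemental feed;
$m > 1$: disease, pollutants; $m = 1$: neutral, the default in the
headline sweeps).

## 6. Aging and growth

Cohorts shift up one age; the terminal class is a plus group that
accumulates survivors. Weights advance along the allometric growth curve
scaled by the growth factor $g_i$:

$$w_{a+1} = w_a + b_2\left(L_{a+1}^{b_1} - L_a^{b_1}\right) g_i,$$

with von Bertalanffy length $L_a = L_\infty(1 - e^{-k(a - t_0)})$. The
increment is floored at zero when a patch is transiently over capacity
(fish do not shrink). The plus-group weight is the abundance-weighted
mean of the incoming cohort's grown weight and the resident weight.

# Farm designs

A design occupies a fraction of the lattice (studied range 0–40%) in one
of two layouts: `one_large`, a single contiguous block, or
`several_small`, 5-patch clusters spread with equal wrapped spacing. The
wrapped lattice is translation invariant, so anchor placement is
immaterial at equilibrium. Farms are introduced instantaneously into the
BAU equilibrium state, and the run continues to a new equilibrium.

# Equilibration and calibration

A run is declared converged when relative changes of total biomass and
total catch both stay below $10^{-6}$ for ten consecutive years (cap 500
years post-introduction). The unfished calibration uses a tighter
$10^{-12}$ tolerance; because the dynamics are homogeneous of degree one
in (carrying capacity, abundance), a single reference run determines the
uniform per-patch $K$ that yields the target unfished system biomass
($10^5$ weight units) exactly, verified by re-simulation.

## Fixture parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `linf`, `k_growth`, `t0` | 100, 0.2, 0 | length, 1/yr, yr | generic teleost growth |
| `b1`, `b2` | 3, $10^{-5}$ | – | cubic length-weight |
| `m_nat` | 0.2 | 1/yr | moderate longevity |
| `max_age`, `age_mature` | 20, 3 | yr | plus group; maturity near 45% of $L_\infty$ |
| `legal_length` | $L(3) \approx 45.1$ | length | legal size at maturity |
| `range_fraction` | 0.28 | – | moderately mobile ($\sigma_m = 7$ patches) |
| `recruit_steepness` $h$ | 0.3 | – | compensatory but not saturated recruitment |
| `fecundity` | 2 | larvae / weight | keeps unfished recruitment inside the compensatory range |
| `move_threshold` $\theta$ | 0.75 | – | emigration complete at 75% crowding |
| `k_multiplier` | 3 | – | farm ceiling vs plain patch |
| `zoi_halfwidth` | $\lceil 2\sigma_m \rceil$ | patches | attraction reach tied to mobility |
| weak `price`, `cost_per_effort` | 1, 83.5 | – | open-access baseline overfished ($B \approx 0.28 B_0$) |

Life-history constants are ordinary textbook magnitudes; the behavioural
and economic constants (`fecundity`, `recruit_steepness`,
`move_threshold`, `cost_per_effort`, `range_fraction`) are calibrated
jointly so that the full scenario sweep reproduces the reference
headline equilibrium percentages (maximum catch gains by regime and
layout, maximum catch loss at the highest attraction, and the minimum
biomass gain at the largest farm area). The acceptance test suite pins
these headline metrics; `scripts/acceptance.R` recomputes them from
scratch.

# Numerical choices

- Equilibria by forward iteration (the map is a contraction near the
  attractors of interest); no matrix solves are needed.
- MSY: 21-point coarse grid on aggregate effort $\in [0, n]$, then
  `stats::optimize` between the bracketing grid points.
- Open access: `stats::optimize` on $[0, \texttt{max\_effort}]$ with
  explicit endpoint comparison, since profit can be monotone.
- All sweeps share the calibration, the MSY effort (per movement rate) and
  the BAU equilibrium (per regime) through caches in `run_grid()`.

# Problem sizes and cost

One scenario is a $100 \times 21$ state iterated a few hundred years:
milliseconds per year, seconds per scenario. The full headline sweep
(8 farm areas $\times$ 5 attraction levels $\times$ 2 layouts $\times$
2 regimes = 160 cells) runs in a few minutes on one CPU.

# Limitations

- One-dimensional ring seascape; no 2-D geometry, depth, or habitat
  heterogeneity outside farms.
- Single stock; no multispecies interactions or farmed-fish escapes.
- Annual time step; within-year dynamics (seasonal growth, pulse fishing)
  are out of scope.
- Deterministic recruitment and environment; no process noise, so
  equilibria are points rather than distributions.
- Open-access effort is myopic (per-year optimisation), not a dynamic
  entry-exit process with capital inertia.
- Farm fitness impacts are folded into natural mortality in farm patches
  only; sublethal effects and ZOI-wide exposure are not modelled.

# Worked example

```{r example}
params <- default_species()
fishery <- default_fishery("strong")
design <- farm_design(0.2, layout = "several_small", attraction = 5)
run <- run_to_equilibrium(sim_config(params = params, fishery = fishery,
                                     design = design))
relative_outcomes(run$farm, run$bau)
```
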