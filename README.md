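# oceanfarm

A deterministic, spatially explicit simulator of a wild fishery interacting
with ocean aquaculture farms. A single age-structured stock lives on a
100-patch wrapped (ring) lattice; farms placed on the lattice act
simultaneously as:

- **aggregation devices** — wild fish are attracted toward farm structure,
- **de facto no-take refuges** — farm patches are closed to fishing and the
  displaced effort is redistributed over the remaining fishable patches,
- **habitat / fitness modifiers** — farm patches carry an elevated
  biomass-growth ceiling, and optionally a natural-mortality multiplier
  (supplemental food vs. disease/pollutant exposure).

Scenarios differ in farm area (0–40% of the seascape), farm layout (several
small 5-patch clusters vs. one large contiguous block), attraction strength,
species mobility, and management regime: **strong** (aggregate effort held
at the maximum-sustainable-yield level) or **weak** (open access; effort
re-optimised myopically each year to maximise current profit). Every
scenario is compared at equilibrium against its business-as-usual (BAU)
baseline — same species and management, no farms — through the ratios

- `delta_b` = equilibrium total biomass / BAU equilibrium biomass,
- `delta_c` = equilibrium total catch / BAU equilibrium catch.

## Model summary

One simulated year applies, in fixed order:

1. **Adult movement** through a wrapped Gaussian kernel
   (`exp(-d^2 / (2 sigma_m^2))`, rows normalised). Emigration is density
   dependent: the fraction of a patch's fish that disperses rises with local
   crowding `bm/K`, so fish stay where there is spare capacity (notably at
   farms, whose ceiling is tripled) and spill over once a patch fills.
   Attraction multiplies the kernel weight of farm-bound moves from the
   farm's zone of influence.
2. **Density-dependent growth factor** `max(0, 1 - bm/K)` per patch.
3. **Recruitment**: larvae proportional to mature biomass, uniform larval
   settlement, per-patch Beverton–Holt survival saturating on the baseline
   habitat capacity.
4. **Effort**: the year's fishing mortality field — constant aggregate
   effort spread by gravity over fishable biomass (strong), or this year's
   profit-maximising aggregate effort (weak). Farm patches are unfishable;
   their effort share is redistributed, conserving aggregate effort.
5. **Harvest**: Baranov catch accounting under the combined exponential
   `Z = M + F * selectivity`, with the farm mortality multiplier folded
   into `M` in farm patches.
6. **Aging** with density-dependent weight growth and a plus group.

Runs continue until biomass and catch change by less than a relative
tolerance for ten consecutive years. The model contains no random numbers:
results are bit-identical across reruns.

## Quick start

```r
library(oceanfarm)

params  <- default_species()            # calibrated generic teleost
fishery <- default_fishery("strong")    # constant effort at MSY
design  <- farm_design(total_fraction = 0.2, layout = "several_small",
                       attraction = 5)

cfg <- sim_config(params = params, fishery = fishery, design = design)
run <- run_to_equilibrium(cfg)
relative_outcomes(run$farm, run$bau)
```

Sweeps over many scenarios share the expensive calibration work:

```r
tab <- run_grid(scenario_grid(farm_fractions = c(0.1, 0.2, 0.4),
                              attraction_levels = c(1, 5, 15),
                              regimes = "strong",
                              layouts = "several_small"))
summarize_max_benefit(tab, "strong", "several_small")
```

## Command line

A thin CLI ships in `inst/cli/oceanfarm`:

```sh
inst/cli/oceanfarm run   --config cfg.yaml --out run.csv
inst/cli/oceanfarm sweep --grid grid.yaml  --out results.csv
inst/cli/oceanfarm msy   --config cfg.yaml
```

Config files are YAML (or JSON) with optional blocks `species:`,
`fishery:`, `farm:` and `simulation:`; see `?read_sim_config`.

## Tests

```r
testthat::test_dir("tests/testthat")
```

The suite covers per-module hand-computed oracles and structural
properties (conservation laws, fixed points, orderings, determinism), plus
an acceptance file that reruns the full sweep and checks the calibrated
headline metrics.
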