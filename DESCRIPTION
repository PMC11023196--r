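Package: oceanfarm
Title: Spatial Age-Structured Simulation of Ocean Aquaculture Effects on Wild Fisheries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A deterministic, spatially explicit, age-structured population and
    fishing simulator for evaluating how ocean aquaculture farms affect wild
    fish stocks and capture fisheries. Farms act simultaneously as fish
    aggregating devices (attraction-biased movement toward farm patches), as
    small no-take refuges (fishing is prohibited inside farms and effort is
    redistributed by a gravity model over fishable biomass), and as modifiers
    of local fitness (carrying-capacity and natural-mortality multipliers).
    The model runs on a one-dimensional wrapped lattice of habitat patches with
    Gaussian adult movement, uniform larval dispersal with per-patch
    Beverton-Holt settlement survival, density-dependent von Bertalanffy
    growth, Baranov catch accounting, and two fishery management regimes:
    constant effort at maximum sustainable yield, and open access with myopic
    profit-maximizing effort. Scenario sweeps report equilibrium biomass and
    catch relative to a no-farm baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
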