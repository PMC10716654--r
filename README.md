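# paleorange

Process-explicit reconstruction of megafauna range and population dynamics
over millennia, with pattern-oriented validation against the fossil record.

`paleorange` is built for quantitative palaeoecologists and conservation
biogeographers who want to ask *why* a species' range collapsed: how much
of the loss was climate, how much hunting, how much land-use change. The
motivating system is the European bison (*Bison bonasus*), which contracted
from a Eurasian-wide late-Pleistocene distribution to two relict
populations by 1850 CE. The package implements the full model chain on
synthetic landscapes with known truth, so every stage is testable and the
calibration machinery can be validated by parameter recovery.

## The model chain

1. **Niche model.** Quality-filtered fossil occurrences (age quality score
   > 10) are intersected with four environmental axes (annual
   precipitation, winter temperature, spring–summer evapotranspiration,
   land-use-adjusted biomass) at every generational step within ±2 s.d. of
   their calibrated age. A product-Gaussian kernel density ("Gaussian
   hypervolume") with cross-validated bandwidth describes the niche;
   realized niches are subsampled by a volume fraction *v* (density-mass
   truncation) and a marginality *m* (centroid displacement). Habitat
   suitability is the projected density scaled by the pooled 95th
   percentile, clipped to 1.

2. **Human pressure.** Gridded effective-population-size surfaces are
   scaled to [0, 1] by their pooled 95th percentile, interpolated from
   25-year to 10-year steps, and realized by lognormal draws truncated to
   the ±1 s.d. envelope, with a window-centre parameter ω ∈ [−1, 1].

3. **Population model (SEPM).** Per cell and 10-year generation:
   carrying capacity K = S · D · A (suitability × maximum density × cell
   area; ≈ 2000 animals per 86.6 × 75.6 km cell at S = 1, D = 0.3 km⁻²),
   Ricker growth N′ = N exp(r(1 − N/K)) with r ~ Normal(r_max, r_sd),
   harvest O = min(h_max·N, h_max·H·N·Nᑫ/(θᑫ + Nᑫ)) interpolating Holling
   type II (q = 1) and type III (q = 2), distance-kernel dispersal with
   friction (zero over ice), and a hard Allee threshold.

4. **Pattern-oriented calibration.** Latin-hypercube parametrizations are
   scored against a multivariate target — fossil occurrence match
   (cell + 8 neighbours, ±2 s.d. age window), refugium persistence penalty
   (years short of 1850 CE), and the refugia count at 1850 CE — by scaled
   Euclidean distance; ABC rejection keeps the best fraction (0.25% of
   10 000 = 25 on the full schedule), with iterative prior refinement,
   a histogram-overlap convergence check, a resampling goodness-of-fit
   test, and inverse-distance ensemble weighting.

5. **Scenarios and drivers.** Counterfactuals (no hunting, no land-use
   change, no human pressure) under common random numbers attribute each
   extirpated cell to a cause; a post-1500 CE harvest-escalation scan is
   validated against the 3560-animal historical estimate for 1870 CE; and
   centennially binned abundance is regressed on temperature, human
   pressure and land-use change with shrinkage thin-plate smooths (`mgcv`)
   plus a model-ID random effect, comparing nested fits by a χ² test on
   twice the ML-criterion difference.

## Worked example

Build a known-truth world (20 × 20 cells, 300 generations), calibrate with
the desk schedule, and inspect the posterior:

```r
library(paleorange)

world <- pom_world(2024)          # landscape + truth simulation + fossils
pom <- run_pom(function(row, s) evaluate_candidate(world, row, s),
               world$priors, round_sizes = c(300, 200, 200),
               tolerance = 0.1, seed = 2024)

range(pom$accepted$h_max)         # accepted maximum harvest rates
world$bundle$params$h_max         # the truth
pom$convergence$statistic         # posterior histogram overlap
```

A complete run of this example is scripted in `analysis/` (numbered
stages: world construction, calibration, ensemble + counterfactual
scenarios + harvest scan, driver analysis, recovery experiment), writing
tables under `results/`. Stage 2 of a run with seed 2024 prints:

```
accepted 20 of 200 models in the final round
posterior h_max: 0.041-0.369 (truth 0.15); volume fraction 0.39-0.91 (truth 0.65)
convergence overlap statistic: 0.45 (converged: FALSE)
goodness-of-fit p-value of the target in the accepted cloud: 1.00
```

Read: the accepted minimum–maximum envelope brackets both truth
parameters; at desk scale (700 simulations) posteriors are deliberately
wide, so the overlap statistic between successive small rounds stays below
the 0.8 convergence threshold, and the goodness-of-fit p-value (> 0.05)
says the validation target is not an outlier relative to the accepted
summaries.

## Repository layout

```
R/            package code: grid/time, synthetic generators, niche model,
              human pressure, SEPM, POM/ABC, scenarios, drivers, I/O,
              pipeline orchestration
src/          Rcpp cores (kernel density, generational simulation loop)
analysis/     numbered narrative driver scripts (01..05)
scripts/      acceptance.R
tests/        testthat suite
vignettes/    methods vignette: model, assumptions, design decisions
```
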