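#!/usr/bin/env Rscript
# Stage 1: build the synthetic calibration world - a landscape with a
# mid-series suitability collapse and recovery, a retreating ice mask, late
# land-use onset, an expanding human field, a known-truth simulation and a
# fossil record sampled from it - and serialize it under results/world/.
#
# The world uses the desk-scale study conditions: a 20 x 20 equal-area grid
# (86.6 x 75.6 km cells) over 300 generations of 10 years.

library(paleorange)

seed <- 2024L
out <- "results/world"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

world <- pom_world(seed)
dir.create("scratch", showWarnings = FALSE)
saveRDS(world, "scratch/world.rds") # working object shared by later stages

# the full landscape series is ~12 MB of CSV; keep the bundle in scratch/
# and re-emit it on demand with write_landscape(world$bundle$landscape, ...)
write_fossils(world$bundle$fossils, file.path(out, "fossils.csv"), world$grid)
write.csv(data.frame(time_bp = world$grid$step_times_bp,
                     truth_total = world$bundle$sim$totals),
          file.path(out, "truth_totals.csv"), row.names = FALSE)

cat(sprintf("world: %d x %d cells, %d generations (%g-%g BP)\n",
            world$grid$n_rows, world$grid$n_cols, world$grid$n_steps,
            world$grid$t_start_bp, world$grid$t_end_bp))
cat(sprintf("truth population: %.0f at start, %.0f at the end; %d fossils (%d pass the quality filter)\n",
            world$bundle$sim$totals[1],
            world$bundle$sim$totals[world$grid$n_steps],
            nrow(world$bundle$fossils),
            nrow(filter_fossils(world$bundle$fossils))))
cat(sprintf("truth parameters: h_max %.2f, volume fraction %.2f, marginality %.2f\n",
            world$bundle$params$h_max, world$bundle$params$volume_fraction,
            world$bundle$params$marginality))
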