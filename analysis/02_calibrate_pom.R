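#!/usr/bin/env Rscript
# Stage 2: desk-profile pattern-oriented calibration. A Latin hypercube of
# 300 parametrizations, then two refinement rounds of 200 with priors
# re-centred on the accepted models; the best 10% per round are kept by ABC
# rejection against the multivariate target (fossil occurrence match,
# refugium persistence penalty, refugia-count mismatch).

library(paleorange)

world <- readRDS("scratch/world.rds")
seed <- 2024L

pom <- run_pom(function(row, s) evaluate_candidate(world, row, s),
               world$priors, round_sizes = c(300, 200, 200),
               tolerance = 0.1, seed = seed)
saveRDS(pom, "scratch/pom.rds")

dir.create("results", showWarnings = FALSE)
write.csv(pom$accepted, "results/accepted_parameters.csv", row.names = FALSE)
final <- pom$rounds[[length(pom$rounds)]]
write.csv(data.frame(distance = final$distances, final$summaries),
          "results/distances.csv", row.names = FALSE)

gof <- goodness_of_fit(final$summaries[final$accepted, , drop = FALSE],
                       paleorange:::perfect_summary(),
                       scales = final$scales, seed = seed)

cat(sprintf("accepted %d of %d models in the final round\n",
            length(final$accepted), nrow(final$params)))
cat(sprintf("posterior h_max: %.3f-%.3f (truth %.2f); volume fraction %.2f-%.2f (truth %.2f)\n",
            min(pom$accepted$h_max), max(pom$accepted$h_max),
            world$bundle$params$h_max,
            min(pom$accepted$volume_fraction), max(pom$accepted$volume_fraction),
            world$bundle$params$volume_fraction))
cat(sprintf("convergence overlap statistic: %.2f (converged: %s)\n",
            pom$convergence$statistic, pom$convergence$converged))
cat(sprintf("goodness-of-fit p-value of the target in the accepted cloud: %.2f\n",
            gof))
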