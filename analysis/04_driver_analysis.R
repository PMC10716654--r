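#!/usr/bin/env Rscript
# Stage 4: centennial binning of the posterior ensemble and penalized
# smooth-regression driver analysis (temperature, human pressure, land-use
# change), with the chi-squared comparison of the additive model against the
# model with pairwise interaction smooths.

library(paleorange)

world <- readRDS("scratch/world.rds")
ens <- readRDS("scratch/ensemble.rds")

binned <- bin_drivers(ens$posterior, world$bundle$landscape,
                      world$bundle$human$mean)
write.csv(binned, "results/binned_drivers.csv", row.names = FALSE)

f0 <- fit_driver_model(binned)
f1 <- fit_driver_model(binned, with_interactions = TRUE)
cmp <- compare_models(f0, f1)

effects <- do.call(rbind, lapply(c("temperature", "human", "landuse"),
                                 function(cv) {
  pe <- driver_partial_effect(f0, cv)
  data.frame(covariate = cv, x = pe$x, effect = pe$effect)
}))
write.csv(effects, "results/partial_effects.csv", row.names = FALSE)

r2 <- summary(f0$fit)$r.sq
cat(sprintf("additive driver model: %d bins, adjusted R^2 %.2f, deviance explained %.0f%%\n",
            f0$n, r2, 100 * summary(f0$fit)$dev.expl))
cat(sprintf("interaction comparison: statistic %.2f, df %.2f, p = %.3g\n",
            cmp$statistic, cmp$df, cmp$p))
for (cv in c("temperature", "human", "landuse")) {
  pe <- effects[effects$covariate == cv, ]
  cat(sprintf("  %s partial effect range: %.1f to %.1f animals\n",
              cv, min(pe$effect), max(pe$effect)))
}
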