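#!/usr/bin/env Rscript
# Stage 5 — shape of trait-gradient relationships.
#
# Posterior-bootstrap GAM/LM classification of how each population's
# competitive traits vary with temperature. Needs the posterior draws, so
# the Monod stage is re-run here with draws kept (the fits are seeded
# identically to stage 3).

library(thermotraits)

seed <- 20240301
rates <- read_rate_table("results/rates_full.csv")
rates <- rates[rates$population %in% sprintf("pop%02d", 1:6), ]

shapes_tab <- NULL
for (rt in unique(rates$resource_type)) {
  bm <- batch_monod(rates[rates$resource_type == rt, ], iterations = 2000,
                    seed = seed, keep_draws = TRUE)
  dl <- thermotraits:::monod_draw_list(bm$fits)
  if (!length(dl)) next
  st <- batch_shapes(dl,
                     family_map = c(rstar = "gamma", alpha = "gamma",
                                    net_mu_max = "gaussian"),
                     n_boot = 200, seed = derive_seed(seed, "shapes", rt))
  st$resource_type <- rt
  shapes_tab <- rbind(shapes_tab, st)
}
write.csv(shapes_tab, "results/shapes.csv", row.names = FALSE)

cat(sprintf("%d trait-gradient relationships classified\n", nrow(shapes_tab)))
print(table(shapes_tab$trait, shapes_tab$label))
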