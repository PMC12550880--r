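#!/usr/bin/env Rscript
# Stage 6 — cross-population trait associations.
#
# Builds the six per-population trait summaries from stages 3-4, then runs
# the ordination (PCA + ANOSIM by phylum), the Kendall correlation matrix,
# the resource-interaction gate for pooling, and the constrained-resampling
# null for correlations with Tmax_max.

library(thermotraits)

seed <- 20240301
monod_tab <- read.csv("results/monod_traits.csv")
tpc_tab <- read.csv("results/tpc_traits.csv")

summary_tab <- summarize_traits(monod_tab, tpc_tab)
write.csv(summary_tab, "results/trait_summary.csv", row.names = FALSE)
cat(sprintf("trait summaries for %d population x resource units\n",
            nrow(summary_tab)))

pca <- run_pca(summary_tab)
cat(sprintf("PCA: PC1+PC2 explain %.1f%% of trait variance (%d rows dropped for missing traits)\n",
            sum(pca$var_explained[1:2]), pca$n_dropped))
write.csv(cbind(pca$meta, pca$scores), "results/pca_scores.csv",
          row.names = FALSE)

phyla <- pca$meta$phylum
if (length(unique(phyla)) >= 2 && all(table(phyla) >= 2)) {
  an <- anosim_groups(pca$scores, phyla, n_perm = 999, seed = seed)
  cat(sprintf("ANOSIM by phylum: R = %.4f, p = %.3f\n", an$R, an$p))
}

km <- kendall_matrix(summary_tab)
write.csv(km$tau, "results/kendall_tau.csv")
sig <- which(km$p < 0.05 & upper.tri(km$p), arr.ind = TRUE)
cat(sprintf("%d of %d trait pairs significantly rank-correlated at 0.05\n",
            nrow(sig), sum(upper.tri(km$p))))

# do thermal maxima covary with the temperature of the lowest R*,
# and is any of that expected from the sampling constraint alone?
ok <- is.finite(summary_tab$Tmax_max) & is.finite(summary_tab$TRstar_min)
if (sum(ok) >= 5) {
  it <- interaction_test(summary_tab$TRstar_min[ok], summary_tab$Tmax_max[ok],
                         summary_tab$resource_type[ok])
  cat(sprintf("resource x Tmax_max interaction p = %.3f (%s)\n",
              it$p_interaction,
              if (!is.null(it$pooled)) "pooled across resources"
              else "kept separate"))
  obs_tau <- suppressWarnings(
    cor(summary_tab$TRstar_min[ok], summary_tab$Tmax_max[ok],
        method = "kendall"))
  nt <- null_tau_distribution(summary_tab$Tmax_max[ok], lower = 15,
                              observed_tau = obs_tau, n_sims = 1000,
                              seed = seed)
  cat(sprintf("TRstar_min ~ Tmax_max: observed tau %.3f sits at percentile %.2f of the constrained null (null mean %.3f)\n",
              obs_tau, nt$percentile, mean(nt$null_tau)))
}
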