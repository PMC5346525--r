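#!/usr/bin/env Rscript
# Stage 4 — the group-level statistical battery.
#
# Covariate-adjusted GLM comparisons of cognitive scores and global
# clustering (BH-FDR over the performance family), Wilcoxon rank test for
# global Hurst, per-region local comparisons with FDR, within-group
# correlations among the three global metrics with between-group Fisher
# r-to-z comparisons, the two-metric PCA component, and the
# log-Mahalanobis cognitive composite correlated with the PCA scores.

library(brainnetdyn)

cohort <- read_cohort("results/data")
metrics <- compute_cohort_metrics(cohort)
stats <- run_statistical_battery(metrics$table, metrics$nodal)

dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)
for (nm in c("cognitive", "global_metrics", "local", "coupling", "pca_mhd",
             "composite", "exploratory")) {
  if (!is.null(stats[[nm]])) {
    write.csv(stats[[nm]], file.path("results/stats", paste0(nm, ".csv")),
              row.names = FALSE)
  }
}
jsonlite::write_json(list(
  pca_loadings = as.list(stats$pca$loadings),
  pca_variance_explained = stats$pca$variance_explained
), "results/stats/pca.json", auto_unbox = TRUE, digits = NA)

cp <- stats$coupling[stats$coupling$var1 == "sc_global_clust" &
                       stats$coupling$var2 == "fc_global_clust", ]
cat(sprintf("SC-FC coupling: r = %.2f (patients, p = %.3f) vs %.2f (controls, p = %.3f)\n",
            cp$r_patient, cp$p_patient, cp$r_control, cp$p_control))
cat(sprintf("Fisher comparison of the two correlations: z = %.2f, p = %.4f\n",
            cp$fisher_z, cp$fisher_p))
gm <- stats$global_metrics
cat(sprintf("Global Hurst rank test: U = %.0f, p = %.3f\n",
            gm$statistic[gm$metric == "global_h"], gm$p[gm$metric == "global_h"]))
cat(sprintf("PCA component 1 explains %.0f%% of SC/FC clustering variance\n",
            100 * stats$pca$variance_explained))
cat(sprintf("PCA score vs log-MHD in patients: r = %.2f, p = %.3f\n",
            stats$pca_mhd$r, stats$pca_mhd$p))
cat(sprintf("Cognitive tests surviving FDR (performance family): %s\n",
            paste(stats$cognitive$measure[!is.na(stats$cognitive$p_fdr) &
                                            stats$cognitive$p_fdr < 0.05],
                  collapse = ", ")))
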