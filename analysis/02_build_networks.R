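#!/usr/bin/env Rscript
# Stage 2 — build the functional and structural connectomes.
#
# Functional: pairwise Pearson correlation of region time courses, Fisher
# r-to-z normalized. Structural: single-subject gray-matter similarity
# networks over 3x3x3 voxel cubes. Both modalities are then characterized
# by their cohort-common minimum connection density (the smallest edge
# density at which every subject's network is one connected component).

library(brainnetdyn)

cohort <- read_cohort("results/data")

fc_mats <- lapply(cohort$timeseries, correlation_matrix)
cubes <- lapply(cohort$gray_matter, extract_cubes,
                gm_threshold = cohort$config$gm_threshold)
sc_mats <- lapply(cubes, build_similarity_matrix)

d_fc <- find_min_density(fc_mats)
d_sc <- find_min_density(sc_mats)

dir.create("results/networks", recursive = TRUE, showWarnings = FALSE)
write_connectivity_matrix(fc_mats[[1]], "results/networks/example_fc_sub001.tsv")
write_connectivity_matrix(sc_mats[[1]], "results/networks/example_sc_sub001.tsv")
write.csv(data.frame(
  subject_id = vapply(cubes, `[[`, "", "subject_id"),
  n_nodes = vapply(cubes, `[[`, 0L, "n_nodes")
), "results/networks/structural_network_sizes.csv", row.names = FALSE)
jsonlite::write_json(
  list(functional = d_fc, structural = d_sc),
  "results/networks/min_connection_densities.json",
  auto_unbox = TRUE, digits = NA)

cat("Functional connectomes: 90 nodes,",
    "minimum connection density", round(d_fc, 4), "\n")
cat("Structural connectomes:", round(mean(vapply(cubes, `[[`, 0L, "n_nodes"))),
    "cube nodes on average (SD",
    round(sd(vapply(cubes, `[[`, 0L, "n_nodes")), 1), "),",
    "minimum connection density", round(d_sc, 4), "\n")
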