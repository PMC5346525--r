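#' Compute per-subject network metrics and Hurst profiles for a cohort
#'
#' The metric core of the pipeline, shared by [run_pipeline()] and the
#' analysis scripts: functional connectomes (Fisher-z correlation
#' matrices), structural gray-matter similarity networks from 3x3x3 voxel
#' cubes, cohort-common minimum-density thresholding (per modality by
#' default), clustering coefficients, label-aggregated structural nodal
#' clustering, and per-region Hurst profiles.
#'
#' @param cohort a `synthetic_cohort` (or compatible list)
#' @param density_policy `"per-modality"` (one common density per
#'   modality, the default) or `"common"` (a single density across both)
#' @param use_rotations maximize cube similarity over the 48 cube
#'   re-orderings?
#' @return list with `table` (cohort table extended with
#'   `fc_global_clust`, `sc_global_clust`, `sc_n_nodes`, `global_h`),
#'   `nodal` (list of subjects x regions matrices: `fc_local_clust`,
#'   `sc_local_clust`, `local_h`), `densities`, `window_base`
#' @export
compute_cohort_metrics <- function(cohort,
                                   density_policy = c("per-modality", "common"),
                                   use_rotations = FALSE) {
  density_policy <- match.arg(density_policy)
  ts_list <- cohort$timeseries
  gm_list <- cohort$gray_matter
  parc <- cohort$parcellation
  n <- length(ts_list)
  stopifnot(n == length(gm_list), n == nrow(cohort$cohort_table))
  region_labels <- ts_list[[1]]$region_labels
  n_regions <- length(region_labels)

  with_subject <- function(id, stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", stage, ", subject ", id, ": ", conditionMessage(e),
           call. = FALSE)
    })
  }
  fc_mats <- lapply(ts_list, function(ts)
    with_subject(ts$subject_id, "functional_network", correlation_matrix(ts)))
  cube_sets <- lapply(gm_list, function(gm)
    with_subject(gm$subject_id, "structural_network",
                 extract_cubes(gm, gm_threshold = cohort$config$gm_threshold)))
  sc_mats <- lapply(cube_sets, function(cs)
    with_subject(cs$subject_id, "structural_network",
                 build_similarity_matrix(cs, use_rotations = use_rotations)))

  d_fc <- find_min_density(fc_mats)
  d_sc <- find_min_density(sc_mats)
  if (density_policy == "common") d_fc <- d_sc <- max(d_fc, d_sc)

  fc_global <- numeric(n)
  sc_global <- numeric(n)
  sc_n_nodes <- integer(n)
  global_h <- numeric(n)
  fc_local <- matrix(NA_real_, n, n_regions,
                     dimnames = list(NULL, region_labels))
  sc_local <- matrix(NA_real_, n, n_regions,
                     dimnames = list(NULL, region_labels))
  local_h <- matrix(NA_real_, n, n_regions,
                    dimnames = list(NULL, region_labels))
  window_base <- NA_integer_
  for (i in seq_len(n)) {
    g_fc <- threshold_at_density(fc_mats[[i]], d_fc)
    cl_fc <- clustering_coefficients(g_fc)
    fc_global[i] <- cl_fc$global
    fc_local[i, ] <- cl_fc$local

    g_sc <- threshold_at_density(sc_mats[[i]], d_sc)
    cl_sc <- clustering_coefficients(g_sc)
    sc_global[i] <- cl_sc$global
    # zero-variance cubes were dropped from the network; the graph nodes
    # correspond to the kept cube indices
    kept <- attr(sc_mats[[i]], "kept_indices")
    sc_n_nodes[i] <- length(kept)
    nodal <- nodal_clustering_by_label(
      g_sc, cube_sets[[i]]$centers[kept, , drop = FALSE], parc,
      labels = region_labels)
    sc_local[i, ] <- nodal$values

    hp <- with_subject(ts_list[[i]]$subject_id, "hurst_dynamics",
                       hurst_profile(ts_list[[i]]))
    global_h[i] <- hp$global_h
    local_h[i, ] <- hp$local_h
    window_base <- hp$window_base
  }
  tab <- cohort$cohort_table
  tab$fc_global_clust <- fc_global
  tab$sc_global_clust <- sc_global
  tab$sc_n_nodes <- sc_n_nodes
  tab$global_h <- global_h
  list(table = tab,
       nodal = list(fc_local_clust = fc_local, sc_local_clust = sc_local,
                    local_h = local_h),
       densities = c(functional = d_fc, structural = d_sc),
       window_base = window_base)
}

#' Run the full analysis pipeline
#'
#' Sequences simulation (or cohort loading), network construction, graph
#' metrics, Hurst dynamics and the statistical battery, optionally writing
#' every stage output plus a provenance record to `out_dir`.
#'
#' @param config a `simulation_config` (the cohort is simulated), or a
#'   `synthetic_cohort` already in memory
#' @param density_policy see [compute_cohort_metrics()]
#' @param use_rotations see [compute_cohort_metrics()]
#' @param composite_scores score set for the Mahalanobis composite
#' @param out_dir optional output directory; when given, writes the cohort
#'   CSV (with metrics), nodal CSVs, statistics CSVs, a JSON summary and a
#'   provenance JSON declaring every file written
#' @return list with `metrics` (from [compute_cohort_metrics()]), `stats`
#'   (from [run_statistical_battery()]), `provenance`
#' @export
run_pipeline <- function(config, density_policy = "per-modality",
                         use_rotations = FALSE,
                         composite_scores = c("ravlt_total",
                                              "ravlt_interference",
                                              "ctmt1", "cowa"),
                         out_dir = NULL) {
  cohort <- if (inherits(config, "synthetic_cohort")) config
            else simulate_cohort(config)
  metrics <- compute_cohort_metrics(cohort, density_policy, use_rotations)
  stats_bundle <- run_statistical_battery(metrics$table, metrics$nodal,
                                          composite_scores = composite_scores)
  cfg_json <- jsonlite::toJSON(unclass(cohort$config), auto_unbox = TRUE,
                               digits = NA)
  provenance <- list(
    config_hash = fnv1a(as.character(cfg_json)),
    seed = cohort$config$seed,
    density_policy = density_policy,
    densities = as.list(metrics$densities),
    window_base = metrics$window_base,
    n_subjects = nrow(metrics$table),
    files = character(0)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    declare <- function(name, writer) {
      path <- file.path(out_dir, name)
      writer(path)
      provenance$files <<- c(provenance$files, name)
    }
    declare("cohort_metrics.csv", function(p)
      utils::write.csv(metrics$table, p, row.names = FALSE))
    for (nm in names(metrics$nodal)) {
      declare(paste0(nm, ".csv"), function(p)
        utils::write.csv(
          data.frame(subject_id = metrics$table$subject_id,
                     metrics$nodal[[nm]], check.names = FALSE),
          p, row.names = FALSE))
    }
    for (nm in c("cognitive", "global_metrics", "local", "coupling",
                 "pca_mhd", "composite", "exploratory")) {
      if (!is.null(stats_bundle[[nm]])) {
        local({
          nm_ <- nm
          declare(paste0("stats_", nm_, ".csv"), function(p)
            utils::write.csv(stats_bundle[[nm_]], p, row.names = FALSE))
        })
      }
    }
    declare("stats_summary.json", function(p)
      jsonlite::write_json(list(
        pca_loadings = as.list(stats_bundle$pca$loadings),
        pca_variance_explained = stats_bundle$pca$variance_explained,
        pca_mhd = as.list(stats_bundle$pca_mhd),
        densities = as.list(metrics$densities)
      ), p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
    declare("config.json", function(p)
      write_simulation_config(cohort$config, p))
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(metrics = metrics, stats = stats_bundle, provenance = provenance)
}
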