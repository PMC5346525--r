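# Tiny FNV-1a hash of a string, for provenance records.
fnv1a <- function(s) {
  h <- 2166136261
  for (code in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write one subject's ROI time series as TSV
#'
#' Time points in rows, regions in columns; the header row carries the
#' region labels.
#'
#' @param ts a `roi_timeseries`
#' @param path output file path
#' @export
write_roi_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  utils::write.table(t(ts$data), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read one subject's ROI time series from TSV
#'
#' @param path TSV written by [write_roi_timeseries()]
#' @param subject_id subject identifier to attach
#' @param tr_seconds repetition time metadata
#' @return a `roi_timeseries`
#' @export
read_roi_timeseries <- function(path, subject_id, tr_seconds = 2.0) {
  d <- utils::read.delim(path, check.names = FALSE)
  roi_timeseries(subject_id, t(as.matrix(d)), region_labels = colnames(d),
                 tr_seconds = tr_seconds)
}

#' Write a connectivity matrix as TSV
#' @param m a `connectivity_matrix`
#' @param path output file path
#' @export
write_connectivity_matrix <- function(m, path) {
  stopifnot(inherits(m, "connectivity_matrix"))
  utils::write.table(m$weights, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
}

#' Serialize a simulation configuration to JSON
#' @param config a `simulation_config`
#' @param path output file path
#' @export
write_simulation_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Read a simulation configuration from JSON
#' @param path JSON written by [write_simulation_config()]
#' @return a `simulation_config`
#' @export
read_simulation_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  raw$cognitive_moments <- as.data.frame(raw$cognitive_moments)
  do.call(simulation_config, raw)
}

#' Write a full synthetic cohort to disk
#'
#' Per-subject time-series TSVs, gray-matter and parcellation NIfTI
#' volumes, the cohort CSV, the JSON truth manifest and a JSON config echo.
#'
#' @param cohort a `synthetic_cohort`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
  dir.create(file.path(dir, "graymatter"), showWarnings = FALSE)
  for (ts in cohort$timeseries) {
    write_roi_timeseries(ts, file.path(dir, "timeseries",
                                       paste0(ts$subject_id, ".tsv")))
  }
  vox <- cohort$config$gm_voxel_mm
  for (gm in cohort$gray_matter) {
    img <- RNifti::asNifti(gm$volume, pixdim = vox)
    RNifti::writeNifti(img, file.path(dir, "graymatter",
                                      paste0(gm$subject_id, "_gm.nii.gz")))
  }
  parc <- RNifti::asNifti(cohort$parcellation + 0L, pixdim = vox)
  RNifti::writeNifti(parc, file.path(dir, "parcellation.nii.gz"))
  utils::write.csv(cohort$cohort_table, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_simulation_config(cohort$config, file.path(dir, "config.json"))
  invisible(dir)
}

#' Regenerate a cohort from its on-disk config echo
#'
#' Reading the config echo and re-simulating reproduces the written cohort
#' exactly (the truth-manifest round-trip property).
#'
#' @param dir directory written by [write_cohort()]
#' @return a `synthetic_cohort`
#' @export
read_cohort <- function(dir) {
  simulate_cohort(read_simulation_config(file.path(dir, "config.json")))
}
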