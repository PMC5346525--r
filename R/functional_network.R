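#' ROI time-series container
#'
#' One subject's region-by-time signal matrix, e.g. resting-state fMRI time
#' courses extracted for the 90 regions of an anatomical atlas.
#'
#' @param subject_id subject identifier
#' @param data numeric matrix, regions in rows, time points in columns
#' @param region_labels unique region names, one per row
#' @param tr_seconds repetition time in seconds (metadata only)
#' @return object of class `roi_timeseries`
#' @export
roi_timeseries <- function(subject_id, data, region_labels = rownames(data),
                           tr_seconds = 2.0) {
  data <- as.matrix(data)
  if (is.null(region_labels)) {
    region_labels <- sprintf("ROI%03d", seq_len(nrow(data)))
  }
  stopifnot(
    nrow(data) >= 2, ncol(data) >= 16,
    all(is.finite(data)),
    length(region_labels) == nrow(data),
    !anyDuplicated(region_labels)
  )
  rownames(data) <- region_labels
  structure(list(subject_id = as.character(subject_id), data = data,
                 region_labels = region_labels, tr_seconds = tr_seconds),
            class = "roi_timeseries")
}

#' Connectivity matrix container
#'
#' Symmetric association weights between nodes (atlas regions for the
#' functional modality, gray-matter cubes for the structural one), zero on
#' the diagonal.
#'
#' @param subject_id subject identifier
#' @param weights symmetric numeric matrix, zero diagonal
#' @param modality `"functional"` or `"structural"`
#' @param node_labels node names
#' @return object of class `connectivity_matrix`
#' @export
connectivity_matrix <- function(subject_id, weights,
                                modality = c("functional", "structural"),
                                node_labels = rownames(weights)) {
  modality <- match.arg(modality)
  weights <- as.matrix(weights)
  stopifnot(
    nrow(weights) == ncol(weights),
    all(is.finite(weights)),
    max(abs(weights - t(weights))) <= 1e-10,
    all(diag(weights) == 0)
  )
  weights <- (weights + t(weights)) / 2
  if (is.null(node_labels)) node_labels <- as.character(seq_len(nrow(weights)))
  dimnames(weights) <- list(node_labels, node_labels)
  structure(list(subject_id = as.character(subject_id), weights = weights,
                 modality = modality, node_labels = node_labels),
            class = "connectivity_matrix")
}

#' Fisher r-to-z transformation
#'
#' Variance-stabilizing transform of a correlation, `atanh(r)`.
#'
#' @param r correlation(s), strictly inside (-1, 1)
#' @return z value(s)
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for the Fisher z transform")
  atanh(r)
}

# Saturation point for correlations before the z transform; keeps z finite
# (about 8.4) for duplicated series.
.r_clip <- 1 - 1e-7

#' Residualize region signals against nuisance confounds
#'
#' Optional hook standing in for motion-parameter regression: each region
#' series is replaced by the residual of an OLS fit on the confound columns
#' (plus intercept) before correlation.
#'
#' @param ts a `roi_timeseries`
#' @param confounds numeric matrix/data frame, one row per time point
#' @return a `roi_timeseries` of residual signals
#' @export
regress_confounds <- function(ts, confounds) {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- as.matrix(confounds)
  stopifnot(nrow(x) == ncol(ts$data), all(is.finite(x)))
  fit <- stats::lm.fit(cbind(1, x), t(ts$data))
  ts$data <- t(fit$residuals)
  rownames(ts$data) <- ts$region_labels
  ts
}

#' Functional connectivity matrix of one subject
#'
#' Pairwise Pearson correlations between all region time courses,
#' normalized by the Fisher r-to-z transformation. Correlations are clipped
#' to +/-(1 - 1e-7) before the transform so duplicated series produce a
#' finite, documented saturation value rather than infinity. The diagonal
#' is zero.
#'
#' @param ts a `roi_timeseries`; every region must have nonzero variance
#' @param confounds optional confound table passed to [regress_confounds()]
#' @return a `connectivity_matrix` of z-scored correlations
#' @export
correlation_matrix <- function(ts, confounds = NULL) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (!is.null(confounds)) ts <- regress_confounds(ts, confounds)
  v <- apply(ts$data, 1L, stats::var)
  if (any(v == 0)) {
    stop("constant region series: ",
         paste(ts$region_labels[v == 0], collapse = ", "))
  }
  r <- stats::cor(t(ts$data))
  r <- pmin(pmax(r, -.r_clip), .r_clip)
  z <- atanh(r)
  diag(z) <- 0
  connectivity_matrix(ts$subject_id, z, "functional", ts$region_labels)
}
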