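#' Gray-matter map container
#'
#' One subject's 3D gray-matter density volume (values in [0, 1], e.g.
#' voxel-based-morphometry output) with an optional analysis mask.
#'
#' @param subject_id subject identifier
#' @param volume 3D numeric array of densities in [0, 1]
#' @param voxel_size_mm length-3 voxel size in millimetres
#' @param mask 3D logical array, same shape; default all TRUE
#' @return object of class `gray_matter_map`
#' @export
gray_matter_map <- function(subject_id, volume, voxel_size_mm = c(3, 3, 3),
                            mask = NULL) {
  stopifnot(length(dim(volume)) == 3, all(is.finite(volume)),
            min(volume) >= 0, max(volume) <= 1)
  if (is.null(mask)) mask <- array(TRUE, dim(volume))
  stopifnot(identical(dim(mask), dim(volume)), is.logical(mask))
  structure(list(subject_id = as.character(subject_id), volume = volume,
                 voxel_size_mm = voxel_size_mm, mask = mask),
            class = "gray_matter_map")
}

#' Tile a gray-matter volume into 3x3x3 cube nodes
#'
#' Nodes of the single-subject structural network are non-overlapping
#' 3x3x3 voxel cubes on a fixed lattice anchored at the volume origin
#' (0-based voxel index (0,0,0)); trailing voxels that do not fill a cube
#' are dropped. A cube becomes a node iff at least `min_gm_voxels` of its
#' 27 voxels have density strictly above `gm_threshold` and lie in the
#' mask; this majority-gray inclusion rule keeps cubes spanning the gray
#' matter while excluding background. The 27 values of each cube are
#' stored in x-fastest raster order (x varies fastest, then y, then z).
#'
#' @param gm a `gray_matter_map`
#' @param gm_threshold density threshold, default 0.1
#' @param min_gm_voxels minimum above-threshold voxels per cube, default 14
#' @return object of class `cube_set`: list with `subject_id`, `centers`
#'   (n x 3 matrix of 0-based center-voxel coordinates, center = cube
#'   anchor + (1,1,1)), `values` (n x 27 matrix), `n_nodes`
#' @export
extract_cubes <- function(gm, gm_threshold = 0.1, min_gm_voxels = 14L) {
  stopifnot(inherits(gm, "gray_matter_map"))
  d <- dim(gm$volume)
  stopifnot(all(d >= 3))
  n_cube <- d %/% 3L
  vol <- gm$volume
  vol[!gm$mask] <- 0
  anchors <- as.matrix(expand.grid(
    x = seq_len(n_cube[1]) * 3L - 3L,
    y = seq_len(n_cube[2]) * 3L - 3L,
    z = seq_len(n_cube[3]) * 3L - 3L
  ))
  off <- as.matrix(expand.grid(dx = 0:2, dy = 0:2, dz = 0:2))  # x-fastest
  vals <- matrix(0.0, nrow(anchors), 27L)
  for (k in seq_len(27L)) {
    idx <- cbind(anchors[, 1] + off[k, 1] + 1L,
                 anchors[, 2] + off[k, 2] + 1L,
                 anchors[, 3] + off[k, 3] + 1L)
    vals[, k] <- vol[idx]
  }
  keep <- rowSums(vals > gm_threshold) >= min_gm_voxels
  if (!any(keep)) stop("no gray-matter cubes")
  structure(list(
    subject_id = gm$subject_id,
    centers = anchors[keep, , drop = FALSE] + 2L,  # anchor + (1,1,1), 1-based
    values = vals[keep, , drop = FALSE],
    n_nodes = sum(keep)
  ), class = "cube_set")
}

# The 48 right-angle rotation/reflection re-orderings of a 3x3x3 cube,
# as permutations of the x-fastest raster index (computed lazily, cached).
.cube_symmetry_cache <- new.env(parent = emptyenv())
cube_symmetries <- function() {
  if (!is.null(.cube_symmetry_cache$perms)) return(.cube_symmetry_cache$perms)
  coords <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",", collapse = ";")
  index_of <- stats::setNames(seq_len(27L), apply(coords, 1, paste, collapse = ","))
  perms <- list()
  seen <- character()
  for (p in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
    for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
      m <- coords[, p, drop = FALSE]
      m[, 1] <- m[, 1] * sx; m[, 2] <- m[, 2] * sy; m[, 3] <- m[, 3] * sz
      k <- key(m)
      if (!k %in% seen) {
        seen <- c(seen, k)
        perms[[length(perms) + 1L]] <-
          unname(index_of[apply(m, 1, paste, collapse = ",")])
      }
    }
  }
  .cube_symmetry_cache$perms <- perms
  perms
}

#' Similarity between two gray-matter cubes
#'
#' Pearson correlation across the 27 paired voxel values: deviations from
#' each cube's mean, normalized by the product of standard deviations. With
#' `use_rotations = TRUE` the similarity is the maximum over the 48
#' right-angle rotation/reflection re-orderings of the second cube, making
#' the measure invariant to cube orientation.
#'
#' @param a,b numeric vectors of 27 values in x-fastest raster order
#' @param use_rotations maximize over cube-b re-orderings?
#' @return similarity in [-1, 1], or NA_real_ if either cube has zero
#'   variance (such node pairs must be excluded by the caller)
#' @export
cube_similarity <- function(a, b, use_rotations = FALSE) {
  stopifnot(length(a) == 27, length(b) == 27)
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  if (!use_rotations) return(stats::cor(a, b))
  max(vapply(cube_symmetries(), function(p) stats::cor(a, b[p]), 0.0))
}

#' Structural similarity matrix across all cube pairs
#'
#' Correlation matrix across all pairs of cube nodes. Zero-variance cubes
#' are dropped first (count recorded in the `n_dropped` attribute). Without
#' rotations the whole matrix is one crossproduct of the standardized cube
#' values; with rotations the maximum correlation over the 48 re-orderings
#' is computed in blocks of whole re-ordered matrices.
#'
#' @param cubes a `cube_set` with >= 2 cubes
#' @param use_rotations maximize similarity over cube re-orderings?
#' @return a `connectivity_matrix` (modality `"structural"`) with attribute
#'   `n_dropped`; node labels are `cube<i>` with i the original cube index
#' @export
build_similarity_matrix <- function(cubes, use_rotations = FALSE) {
  stopifnot(inherits(cubes, "cube_set"), cubes$n_nodes >= 2)
  v <- cubes$values
  labs <- sprintf("cube%05d", seq_len(nrow(v)))
  sds <- apply(v, 1L, stats::sd)
  keep <- sds > 0
  n_dropped <- sum(!keep)
  v <- v[keep, , drop = FALSE]
  labs <- labs[keep]
  if (nrow(v) < 2) stop("fewer than 2 cubes with nonzero variance")
  std <- (v - rowMeans(v)) / (apply(v, 1L, stats::sd) * sqrt(26))
  if (!use_rotations) {
    s <- tcrossprod(std)
  } else {
    s <- matrix(-Inf, nrow(v), nrow(v))
    for (p in cube_symmetries()) {
      vp <- v[, p, drop = FALSE]
      stdp <- (vp - rowMeans(vp)) / (apply(vp, 1L, stats::sd) * sqrt(26))
      s <- pmax(s, tcrossprod(std, stdp))
    }
    s <- pmax(s, t(s))  # max over orderings of either member is symmetric
  }
  s[s > 1] <- 1; s[s < -1] <- -1
  diag(s) <- 0
  out <- connectivity_matrix(cubes$subject_id, s, "structural", labs)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "kept_indices") <- which(keep)
  out
}

#' Aggregate cube-level clustering to atlas labels
#'
#' Each cube node takes the parcellation label of its center voxel;
#' background cubes (label 0) stay in the graph but are excluded from the
#' aggregation. The per-label value is the mean cube-level clustering
#' coefficient over cubes carrying that label; a label present in the
#' parcellation but with no cubes is reported as NA (missing), never zero.
#'
#' @param graph a `binary_graph` whose nodes correspond 1:1 to the rows of
#'   `cube_centers`
#' @param cube_centers n x 3 matrix of 1-based center-voxel coordinates
#' @param parcellation 3D integer array of labels, 0 = background
#' @param labels optional label names, one per parcel 1..max
#' @return object of class `nodal_clustering`: list with `subject_id`
#'   (taken from `graph`'s labels attribute if present), `values` (named
#'   per-label mean clustering), `n_background`
#' @export
nodal_clustering_by_label <- function(graph, cube_centers, parcellation,
                                      labels = NULL) {
  stopifnot(inherits(graph, "binary_graph"),
            nrow(cube_centers) == nrow(graph$adjacency))
  cube_labels <- parcellation[as.matrix(cube_centers)]
  local <- clustering_coefficients(graph)$local
  n_parcels <- max(parcellation)
  if (is.null(labels)) labels <- sprintf("ROI%03d", seq_len(n_parcels))
  stopifnot(length(labels) == n_parcels)
  values <- vapply(seq_len(n_parcels), function(l) {
    sel <- cube_labels == l
    if (!any(sel)) NA_real_ else mean(local[sel])
  }, 0.0)
  names(values) <- labels
  structure(list(values = values, cube_labels = cube_labels,
                 n_background = sum(cube_labels == 0)),
            class = "nodal_clustering")
}
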