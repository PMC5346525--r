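#' Binary graph at a stated edge density
#'
#' @param adjacency symmetric logical matrix, FALSE diagonal
#' @param density achieved edge density 2E / (N(N-1))
#' @param node_labels node names
#' @return object of class `binary_graph`
#' @export
binary_graph <- function(adjacency, density, node_labels = rownames(adjacency)) {
  adjacency <- adjacency | t(adjacency)
  diag(adjacency) <- FALSE
  if (is.null(node_labels)) node_labels <- as.character(seq_len(nrow(adjacency)))
  dimnames(adjacency) <- list(node_labels, node_labels)
  structure(list(adjacency = adjacency, density = density,
                 node_labels = node_labels),
            class = "binary_graph")
}

# Edge list of the upper triangle sorted for thresholding: positive weights
# only, decreasing weight, ties broken by (row, column) lexicographic order.
ranked_positive_edges <- function(weights) {
  n <- nrow(weights)
  ut <- which(upper.tri(weights), arr.ind = TRUE)
  w <- weights[ut]
  pos <- w > 0
  ut <- ut[pos, , drop = FALSE]
  w <- w[pos]
  o <- order(-w, ut[, 1], ut[, 2])
  list(edges = ut[o, , drop = FALSE], weights = w[o], n_possible = n * (n - 1) / 2)
}

#' Threshold a connectivity matrix at an edge density
#'
#' Keeps the `floor(density * N(N-1)/2)` strongest positive edges; negative
#' weights are excluded before ranking (correlation-graph convention) and
#' ties are broken by (row, column) lexicographic order. Errors if fewer
#' positive weights exist than edges requested.
#'
#' @param m a `connectivity_matrix`
#' @param density target edge density in (0, 1]
#' @return a `binary_graph`
#' @export
threshold_at_density <- function(m, density) {
  stopifnot(inherits(m, "connectivity_matrix"), density > 0, density <= 1)
  r <- ranked_positive_edges(m$weights)
  # small epsilon so a density returned as k/n_possible recovers exactly k
  k <- floor(density * r$n_possible + 1e-9)
  if (length(r$weights) < k) {
    stop("only ", length(r$weights), " positive weights available but ",
         k, " edges requested (shortfall ", k - length(r$weights), ")")
  }
  n <- nrow(m$weights)
  adj <- matrix(FALSE, n, n)
  if (k > 0) {
    e <- r$edges[seq_len(k), , drop = FALSE]
    adj[e] <- TRUE
  }
  binary_graph(adj, density = k / r$n_possible, node_labels = m$node_labels)
}

# Smallest number of top-ranked edges whose graph is one connected
# component (binary search over the ranked edge list).
min_connecting_edges <- function(weights) {
  r <- ranked_positive_edges(weights)
  n <- nrow(weights)
  connected_at <- function(k) {
    e <- r$edges[seq_len(k), , drop = FALSE]
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    igraph::is_connected(g)
  }
  if (length(r$weights) < n - 1 || !connected_at(length(r$weights))) {
    stop("network never becomes fully connected from its positive weights")
  }
  lo <- n - 1L
  hi <- length(r$weights)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (connected_at(mid)) hi <- mid else lo <- mid + 1L
  }
  hi
}

#' Cohort-common minimum connection density
#'
#' For each subject's connectivity matrix, finds the smallest edge density
#' at which the thresholded graph (top-ranked positive edges, same ranking
#' as [threshold_at_density()]) forms a single connected component, then
#' returns the maximum over subjects: the smallest common density at which
#' every subject's network is fully connected.
#'
#' @param matrices list of `connectivity_matrix` objects
#' @return the cohort-common minimum density
#' @export
find_min_density <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  per_subject <- vapply(matrices, function(m) {
    stopifnot(inherits(m, "connectivity_matrix"))
    n <- nrow(m$weights)
    min_connecting_edges(m$weights) / (n * (n - 1) / 2)
  }, 0.0)
  max(per_subject)
}

#' Local and global clustering coefficients
#'
#' The local clustering coefficient of node i is the ratio of actual to
#' possible connections between its neighbors, `2 T_i / (k_i (k_i - 1))`
#' with T_i the triangles through i and k_i its degree; nodes with degree
#' < 2 get 0. The global coefficient is the arithmetic mean of the local
#' values over all nodes — a measure of network segregation.
#'
#' @param g a `binary_graph` with at least 3 nodes
#' @return object of class `clustering_result`: list with `local` (named
#'   numeric) and `global`
#' @export
clustering_coefficients <- function(g) {
  stopifnot(inherits(g, "binary_graph"), nrow(g$adjacency) >= 3)
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  local <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
  names(local) <- g$node_labels
  structure(list(local = local, global = mean(local)),
            class = "clustering_result")
}
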