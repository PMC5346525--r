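# Shared fixtures: small cohorts and independent oracles used across files.

# Desk-scale config shrunk further for unit tests.
tiny_config <- function(seed = 42, ...) {
  simulation_config(n_patients = 6, n_controls = 6, seed = seed, ...)
}

# Independent O(N^3) clustering oracle: triangle enumeration per node.
brute_force_clustering <- function(adj) {
  n <- nrow(adj)
  local <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ])
    k <- length(nb)
    if (k < 2) next
    tri <- 0L
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]]) tri <- tri + 1L
      }
    }
    local[i] <- 2 * tri / (k * (k - 1))
  }
  local
}

# Textbook Pearson correlation over paired values, written independently of
# stats::cor.
brute_force_pearson <- function(a, b) {
  da <- a - sum(a) / length(a)
  db <- b - sum(b) / length(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# Random symmetric connectivity matrix with zero diagonal.
random_connectivity <- function(n, seed, subject_id = "subX") {
  set.seed(seed)
  w <- matrix(stats::rnorm(n * n), n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  connectivity_matrix(subject_id, w)
}

# Random Erdos-Renyi binary graph.
random_er_graph <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(FALSE, n, n)
  adj[upper.tri(adj)] <- stats::runif(n * (n - 1) / 2) < p
  binary_graph(adj | t(adj), density = p)
}

# Pair of series whose sample correlation is exactly r (Gram-Schmidt).
exact_correlation_pair <- function(n, r, seed) {
  set.seed(seed)
  x <- stats::rnorm(n)
  e <- stats::rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  e <- stats::residuals(stats::lm(e ~ x))
  e <- (e - mean(e)) / stats::sd(e)
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}
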