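test_that("cube tiling matches closed-form and brute-force counts", {
  gm <- gray_matter_map("s", array(1, c(6, 6, 6)))
  cs <- extract_cubes(gm, 0.1)
  expect_identical(cs$n_nodes, 8L)   # 2 x 2 x 2 tiling

  expect_error(extract_cubes(gray_matter_map("s", array(0, c(6, 6, 6)))),
               "no gray-matter cubes")

  # half-filled volume: independent voxel-scan oracle
  set.seed(10)
  vol <- array(runif(9 * 9 * 9), c(9, 9, 9))
  vol[1:4, , ] <- 0
  gm2 <- gray_matter_map("s", vol)
  cs2 <- extract_cubes(gm2, 0.1)
  oracle <- 0L
  for (x in seq(1, 7, by = 3)) for (y in seq(1, 7, by = 3)) {
    for (z in seq(1, 7, by = 3)) {
      v <- vol[x:(x + 2), y:(y + 2), z:(z + 2)]
      if (sum(v > 0.1) >= 14) oracle <- oracle + 1L
    }
  }
  expect_identical(cs2$n_nodes, oracle)
})

test_that("cube values use x-fastest raster order anchored at origin", {
  vol <- array(seq_len(27), c(3, 3, 3))   # R arrays are already x-fastest
  gm <- gray_matter_map("s", vol / 27)
  cs <- extract_cubes(gm, 0.1)
  expect_identical(cs$n_nodes, 1L)
  expect_equal(cs$values[1, ], seq_len(27) / 27)
  expect_equal(cs$centers[1, ], c(x = 2, y = 2, z = 2))
})

test_that("cube similarity is Pearson over 27 values with invariances", {
  set.seed(3)
  a <- runif(27); b <- runif(27)
  expect_equal(cube_similarity(a, a), 1, tolerance = 1e-12)
  expect_equal(cube_similarity(a, -(a - mean(a))), -1, tolerance = 1e-12)
  expect_equal(cube_similarity(a, b), brute_force_pearson(a, b),
               tolerance = 1e-12)
  expect_equal(cube_similarity(a + 5, b), cube_similarity(a, b),
               tolerance = 1e-12)
  expect_equal(cube_similarity(3 * a, b), cube_similarity(a, b),
               tolerance = 1e-12)
  expect_true(is.na(cube_similarity(rep(1, 27), b)))
})

test_that("rotation maximization never decreases similarity", {
  set.seed(4)
  for (i in 1:25) {
    a <- rnorm(27); b <- rnorm(27)
    expect_gte(cube_similarity(a, b, use_rotations = TRUE),
               cube_similarity(a, b))
  }
  # rotating b by one of the 48 symmetries leaves the maximized value alone
  a <- rnorm(27); b <- rnorm(27)
  perm <- brainnetdyn:::cube_symmetries()[[10]]
  expect_equal(cube_similarity(a, b[perm], use_rotations = TRUE),
               cube_similarity(a, b, use_rotations = TRUE), tolerance = 1e-12)
})

test_that("similarity matrix equals the naive double loop and is symmetric", {
  set.seed(6)
  vals <- matrix(runif(40 * 27), 40)
  cs <- structure(list(subject_id = "s", centers = matrix(2, 40, 3),
                       values = vals, n_nodes = 40L), class = "cube_set")
  m <- build_similarity_matrix(cs)
  expect_equal(m$weights, t(m$weights))
  oracle <- matrix(0, 40, 40)
  for (i in 1:39) for (j in (i + 1):40) {
    oracle[i, j] <- oracle[j, i] <- brute_force_pearson(vals[i, ], vals[j, ])
  }
  expect_equal(unname(m$weights), oracle, tolerance = 1e-12)

  # identical cubes correlate at 1; zero-variance cubes are dropped, counted
  v3 <- matrix(rep(runif(27), 3), 3, byrow = TRUE)
  cs3 <- structure(list(subject_id = "s", centers = matrix(2, 3, 3),
                        values = rbind(v3, rep(1, 27)), n_nodes = 4L),
                   class = "cube_set")
  m3 <- build_similarity_matrix(cs3)
  expect_identical(attr(m3, "n_dropped"), 1L)
  expect_identical(attr(m3, "kept_indices"), 1:3)   # maps graph to cubes
  expect_equal(unname(m3$weights[upper.tri(m3$weights)]), rep(1, 3),
               tolerance = 1e-10)
})

test_that("rotation-maximized matrix agrees with pairwise maximization", {
  set.seed(7)
  vals <- matrix(rnorm(12 * 27), 12)
  cs <- structure(list(subject_id = "s", centers = matrix(2, 12, 3),
                       values = vals, n_nodes = 12L), class = "cube_set")
  m <- build_similarity_matrix(cs, use_rotations = TRUE)
  for (i in 1:4) for (j in 5:8) {
    expect_equal(m$weights[i, j],
                 cube_similarity(vals[i, ], vals[j, ], use_rotations = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("label aggregation averages cube clustering per parcel", {
  # toy fixture: 6 cubes in 3 parcels on a 9x3x3 parcellation
  parc <- array(0L, c(9, 3, 3))
  parc[1:3, , ] <- 1L; parc[4:6, , ] <- 2L; parc[7:9, , ] <- 3L
  centers <- cbind(c(2, 2, 5, 5, 8, 8), 2, 2)
  adj <- matrix(FALSE, 6, 6)
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(4, 5))
  adj[edges] <- TRUE
  g <- binary_graph(adj, density = 0.33)
  nc <- nodal_clustering_by_label(g, centers, parc, labels = c("L1", "L2", "L3"))
  expected_local <- brute_force_clustering(g$adjacency)
  expect_equal(unname(nc$values["L1"]), mean(expected_local[1:2]))
  expect_equal(unname(nc$values["L2"]), mean(expected_local[3:4]))
  expect_equal(unname(nc$values["L3"]), mean(expected_local[5:6]))

  # complete graph, one label -> 1; edgeless -> 0; empty parcel -> NA
  adj_k <- matrix(TRUE, 4, 4); diag(adj_k) <- FALSE
  parc1 <- array(1L, c(3, 3, 3))
  gk <- binary_graph(adj_k, density = 1)
  c4 <- cbind(rep(2, 4), 2, 2)
  expect_equal(unname(nodal_clustering_by_label(gk, c4, parc1,
                                                labels = "L1")$values), 1)
  ge <- binary_graph(matrix(FALSE, 4, 4), density = 0)
  parc2 <- array(rep(c(1L, 2L), length.out = 27), c(3, 3, 3))
  parc2[2, 2, 2] <- 1L
  vals0 <- nodal_clustering_by_label(ge, c4, parc2,
                                     labels = c("L1", "L2"))$values
  expect_equal(unname(vals0["L1"]), 0)
  expect_true(is.na(vals0["L2"]))   # parcel with no cube centers
})

test_that("background cubes stay in the graph but out of the aggregation", {
  parc <- array(0L, c(6, 3, 3))
  parc[4:6, , ] <- 1L
  adj <- matrix(TRUE, 3, 3); diag(adj) <- FALSE
  g <- binary_graph(adj, density = 1)
  centers <- cbind(c(2, 5, 5), 2, 2)   # first cube in background
  nc <- nodal_clustering_by_label(g, centers, parc, labels = "L1")
  expect_identical(nc$n_background, 1L)
  expect_equal(unname(nc$values["L1"]), 1)
})
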