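random_symmetric <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m + t(m)
}

test_that("density thresholding keeps exactly the strongest pairs", {
  m <- random_symmetric(30, 1)
  g <- threshold_by_density(m, 0.4)
  expect_equal(sum(unclass(g)) / 2, 174)            # round(0.4 * 435)
  g1 <- threshold_by_density(m, 1.0)
  expect_true(all(g1[upper.tri(g1)] == 1))          # complete graph

  m4 <- random_symmetric(4, 2)
  g4 <- threshold_by_density(m4, 0.5)
  kept <- which(upper.tri(m4))[order(-m4[upper.tri(m4)])[1:3]]
  expect_true(all(g4[kept] == 1))
  expect_equal(sum(unclass(g4)) / 2, 3)

  expect_error(threshold_by_density(m4, 0.01), "0 of")
  expect_error(threshold_by_density(m4, 0), "density")
})

test_that("edge counts are exact and nested over the full density grid", {
  m <- random_symmetric(30, 3)
  dens <- seq(0.10, 0.50, by = 0.05)
  prev <- NULL
  for (d in dens) {
    g <- threshold_by_density(m, d)
    expect_equal(sum(unclass(g)) / 2, round(d * 435))
    if (!is.null(prev)) expect_true(all(unclass(g)[prev == 1] == 1))
    prev <- unclass(g)
  }
})

test_that("tie-breaking at the cutoff is deterministic by pair index", {
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- c(0.9, 0.5, 0.5, 0.5, 0.5, 0.1)
  m <- m + t(m)
  g <- threshold_by_density(m, 2 / 6)
  expect_identical(unclass(g), t(unclass(g)))
  expect_equal(sum(unclass(g)) / 2, 2)
  expect_equal(g[1, 2], 1L)                 # strongest pair
  expect_equal(g[1, 3], 1L)                 # first tied pair in index order
})

test_that("clustering and path length match brute-force oracles on canonical graphs", {
  tri <- structure(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3),
                   class = c("binary_graph", "matrix", "array"))
  path3 <- structure(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3),
                     class = c("binary_graph", "matrix", "array"))
  expect_equal(clustering_coefficient(tri), 1)
  expect_equal(clustering_coefficient(path3), 0)
  expect_equal(characteristic_path_length(tri), 1)
  expect_equal(characteristic_path_length(path3), 4 / 3)

  ring5 <- watts_strogatz_adjacency(5, 2, 0)
  expect_equal(characteristic_path_length(
    structure(ring5, class = c("binary_graph", "matrix", "array"))), 1.5)

  # square with one diagonal plus a pendant node
  g5 <- matrix(0L, 5, 5)
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3), c(4, 5))
  for (i in seq_len(nrow(edges))) {
    g5[edges[i, 1], edges[i, 2]] <- g5[edges[i, 2], edges[i, 1]] <- 1L
  }
  g5 <- structure(g5, class = c("binary_graph", "matrix", "array"))
  expect_equal(clustering_coefficient(g5), oracle_clustering(g5))
  expect_equal(characteristic_path_length(g5), oracle_path_length(g5))
})

test_that("metrics equal exhaustive oracles across all 6-node graphs with edges", {
  graphs <- enumerate_graphs(5)        # all 1024 graphs on 5 nodes
  graphs <- c(graphs, enumerate_graphs(6, max_graphs = 512, seed = 4))
  for (adj in graphs) {
    if (sum(adj) == 0) next
    g <- structure(adj, class = c("binary_graph", "matrix", "array"))
    expect_equal(clustering_coefficient(g), oracle_clustering(adj),
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(characteristic_path_length(g)),
                 oracle_path_length(adj), tolerance = 1e-12)
  }
})

test_that("degree-preserving rewiring keeps every degree and forbids self-loops", {
  ws <- watts_strogatz_adjacency(30, 8, 0.1, seed = 5)
  g <- structure(ws, class = c("binary_graph", "matrix", "array"))
  rw <- maslov_sneppen_rewire(g, n_swap_factor = 10, seed = 6)
  expect_equal(rowSums(unclass(rw)), rowSums(ws))
  expect_true(all(diag(unclass(rw)) == 0))
  expect_true(all(unclass(rw) %in% 0:1))
  expect_gt(sum(unclass(rw) != ws), 0)      # topology actually changed
  # same seed reproduces the same rewiring
  rw2 <- maslov_sneppen_rewire(g, n_swap_factor = 10, seed = 6)
  expect_identical(unclass(rw), unclass(rw2))

  # graphs whose degree sequence admits no swap are returned unchanged
  complete <- structure(matrix(1L, 5, 5) - diag(1L, 5),
                        class = c("binary_graph", "matrix", "array"))
  expect_equal(unclass(maslov_sneppen_rewire(complete, seed = 1)),
               unclass(complete), ignore_attr = TRUE)
  star <- matrix(0L, 5, 5); star[1, 2:5] <- 1L; star <- star + t(star)
  star <- structure(star, class = c("binary_graph", "matrix", "array"))
  expect_equal(unclass(maslov_sneppen_rewire(star, seed = 1)), unclass(star),
               ignore_attr = TRUE)
})

test_that("small-worldness is 1 for complete graphs and behaves across regimes", {
  complete <- structure(matrix(1L, 8, 8) - diag(1L, 8),
                        class = c("binary_graph", "matrix", "array"))
  swc <- small_worldness(complete, n_null = 3, seed = 7)
  expect_equal(swc$SW, 1, tolerance = 1e-12)

  er <- erdos_renyi(30, 0.3, seed = 8)
  swe <- small_worldness(er, n_null = 10, seed = 9)
  expect_gt(swe$SW, 0.8)                   # ER is its own approximate null
  expect_lt(swe$SW, 1.2)

  ws <- structure(watts_strogatz_adjacency(30, 8, 0.1, seed = 10),
                  class = c("binary_graph", "matrix", "array"))
  sww <- small_worldness(ws, n_null = 10, seed = 11)
  expect_gt(sww$SW, 1)                     # canonical small-world regime
})

test_that("mean small-worldness peaks at intermediate rewiring and falls to ~1", {
  betas <- c(0.01, 0.1, 1)
  sw <- sapply(betas, function(b) {
    mean(sapply(1:4, function(r) {
      g <- structure(watts_strogatz_adjacency(30, 8, b, seed = 100 * r + round(100 * b)),
                     class = c("binary_graph", "matrix", "array"))
      small_worldness(g, n_null = 5, seed = r)$SW
    }))
  })
  expect_gt(sw[2], 0.9 * sw[1])            # intermediate regime not below lattice
  expect_gt(sw[2], sw[3])                  # and above fully random
  expect_lt(abs(sw[3] - 1), 0.25)          # random graph ~ its own null
})

test_that("Erdos-Renyi sampling matches its binomial edge-count law", {
  expect_true(all(unclass(erdos_renyi(10, 1, seed = 1))[upper.tri(diag(10))] == 1))
  expect_equal(sum(unclass(erdos_renyi(10, 0, seed = 1))), 0)
  counts <- sapply(1:200, function(i) sum(unclass(erdos_renyi(30, 0.4, seed = i))) / 2)
  se <- sqrt(435 * 0.4 * 0.6) / sqrt(200)
  expect_lt(abs(mean(counts) - 174), 3 * se + 1)
})

test_that("a density sweep returns one metrics row per density", {
  m <- random_symmetric(20, 12)
  sweep9 <- suppressWarnings(density_sweep(m, seed = 13, n_null = 3))
  expect_equal(nrow(sweep9), 9)
  expect_equal(sweep9$density, seq(0.10, 0.50, by = 0.05))
  one <- suppressWarnings(density_sweep(m, densities = 0.4, seed = 13, n_null = 3))
  expect_equal(nrow(one), 1)
  expect_error(density_sweep(m, densities = c(0.3, 0.2)), "increasing")
})

test_that("disconnected graphs warn and average reachable pairs only", {
  two <- matrix(0L, 4, 4)
  two[1, 2] <- two[2, 1] <- two[3, 4] <- two[4, 3] <- 1L
  g <- structure(two, class = c("binary_graph", "matrix", "array"))
  expect_warning(L <- characteristic_path_length(g), "disconnected")
  expect_equal(L, 1)
  empty <- structure(matrix(0L, 3, 3), class = c("binary_graph", "matrix", "array"))
  expect_error(characteristic_path_length(empty), "no edges")
})
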