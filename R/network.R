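#' Proportional density thresholding of a connectivity matrix
#'
#' Keeps the `E = round(density * n(n-1)/2)` strongest channel pairs as
#' unweighted edges and removes all others, so every subject's graph has the
#' same density and metric differences reflect topology rather than overall
#' connectivity strength. Ties at the cutoff value are broken by ascending
#' channel-pair index, deterministically.
#'
#' @param m symmetric numeric matrix (e.g. a `connectivity_matrix`).
#' @param density fraction of possible edges to retain, in `(0, 1]`.
#' @return An object of class `binary_graph`: the 0/1 adjacency matrix with
#'   attributes `density` (requested) and `n_edges`.
#' @examples
#' w <- matrix(runif(16), 4, 4); w <- (w + t(w)) / 2; diag(w) <- 0
#' threshold_by_density(w, 0.5)
#' @export
threshold_by_density <- function(m, density) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m))
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  n <- nrow(m)
  ut <- which(upper.tri(m))
  n_pairs <- length(ut)
  n_edges <- as.integer(round_half_away(density * n_pairs))
  if (n_edges < 1L) {
    stop(sprintf("density %g keeps 0 of %d edges", density, n_pairs))
  }
  w <- m[ut]
  keep <- ut[order(-w, seq_along(w))[seq_len(n_edges)]]
  adj <- matrix(0L, n, n, dimnames = dimnames(m))
  adj[keep] <- 1L
  adj <- adj + t(adj)
  structure(adj, class = c("binary_graph", "matrix", "array"),
            density = density, n_edges = n_edges)
}

as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(unclass(adj) != 0, mode = "undirected",
                                      diag = FALSE)
}

binary_graph_from_igraph <- function(g, template) {
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  storage.mode(adj) <- "integer"
  dimnames(adj) <- dimnames(template)
  structure(adj, class = c("binary_graph", "matrix", "array"),
            density = attr(template, "density"),
            n_edges = sum(adj) / 2L)
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges (density %.3f)\n",
              nrow(x), sum(unclass(x)) / 2, attr(x, "density") %||%
                (sum(unclass(x)) / (nrow(x) * (nrow(x) - 1)))))
  invisible(x)
}

#' Mean local clustering coefficient
#'
#' Average over all nodes of the fraction of a node's neighbour pairs that
#' are themselves connected; nodes of degree < 2 contribute 0.
#'
#' @param graph a `binary_graph` (or plain 0/1 adjacency matrix).
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(graph) {
  g <- as_igraph(graph)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(cc)
}

#' Characteristic path length
#'
#' Mean breadth-first shortest-path length over all ordered node pairs,
#' excluding self-pairs. If the graph is disconnected, only reachable pairs
#' are averaged and a warning is emitted (the study's density grid is chosen
#' to keep graphs connected, so this is an edge-case policy).
#'
#' @param graph a `binary_graph`.
#' @return Scalar `>= 1` for any graph with at least one edge.
#' @export
characteristic_path_length <- function(graph) {
  g <- as_igraph(graph)
  if (igraph::ecount(g) == 0L) stop("graph has no edges; path length undefined")
  d <- igraph::distances(g)
  d <- d[row(d) != col(d)]
  finite <- is.finite(d)
  if (!all(finite)) {
    warning("graph is disconnected; averaging reachable pairs only")
  }
  mean(d[finite])
}

#' Degree-preserving (Maslov-Sneppen) rewiring
#'
#' Randomizes topology by repeated double-edge swaps that reject self-loops
#' and duplicate edges, leaving every node's degree exactly unchanged.
#' Graphs admitting no valid swap (complete graphs, stars) are returned
#' unchanged.
#'
#' @param graph a `binary_graph` with at least 2 edges.
#' @param n_swap_factor attempted swaps per edge (default 10).
#' @param seed optional integer seed for reproducible rewiring.
#' @return A rewired `binary_graph` with the same degree sequence.
#' @export
maslov_sneppen_rewire <- function(graph, n_swap_factor = 10, seed = NULL) {
  g <- as_igraph(graph)
  ne <- igraph::ecount(g)
  if (ne < 2L) stop("rewiring needs at least 2 edges")
  gr <- with_seed(seed, igraph::rewire(
    g, igraph::keeping_degseq(loops = FALSE, niter = n_swap_factor * ne)))
  binary_graph_from_igraph(gr, graph)
}

#' Small-world metrics against degree-matched null models
#'
#' Computes clustering coefficient `C` and characteristic path length `L` of
#' the input graph, their means `C_rand`, `L_rand` over `n_null` independent
#' Maslov-Sneppen rewirings, and the small-worldness ratio
#' `SW = (C / C_rand) / (L / L_rand)`; `SW > 1` indicates small-world
#' organization. `C_rand` averages all drawn realizations, including any
#' with zero clustering; if every one of the first `n_null` draws has zero
#' clustering, sampling continues (up to `max_retry` extra draws) until a
#' triangle-bearing realization appears, so the ratio stays defined for
#' sparse graphs whose randomizations are usually triangle-free. An input
#' graph with zero clustering short-circuits to `SW = 0`.
#'
#' @param graph a `binary_graph` with at least 2 edges.
#' @param n_null number of null realizations (default 10).
#' @param n_swap_factor attempted swaps per edge in each rewiring.
#' @param seed optional integer seed.
#' @param max_retry cap on extra null draws when all of the first `n_null`
#'   realizations have zero clustering.
#' @return An object of class `small_world_metrics`: list with `C`, `L`,
#'   `C_rand`, `L_rand`, `C_norm`, `L_norm`, `SW`, `connected`, `density`.
#' @export
small_worldness <- function(graph, n_null = 10, n_swap_factor = 10, seed = NULL,
                            max_retry = 100) {
  C <- clustering_coefficient(graph)
  L <- characteristic_path_length(graph)
  g <- as_igraph(graph)
  connected <- igraph::is_connected(g)
  c_null <- l_null <- numeric(0)
  draw <- function(i) {
    null_g <- maslov_sneppen_rewire(graph, n_swap_factor, child_seed(seed, i))
    c(clustering_coefficient(null_g),
      suppressWarnings(characteristic_path_length(null_g)))
  }
  for (i in seq_len(n_null)) {
    cl <- draw(i)
    c_null <- c(c_null, cl[1])
    l_null <- c(l_null, cl[2])
  }
  if (C > 0) {
    extra <- 0
    while (all(c_null == 0) && extra < max_retry) {
      extra <- extra + 1
      cl <- draw(n_null + extra)
      c_null <- c(c_null, cl[1])
      l_null <- c(l_null, cl[2])
    }
    if (all(c_null == 0)) {
      stop("no triangle-bearing null realization found in ",
           n_null + max_retry, " draws")
    }
  }
  C_rand <- mean(c_null)
  L_rand <- mean(l_null)
  if (C == 0) {
    return(structure(list(C = 0, L = L, C_rand = C_rand, L_rand = L_rand,
                          C_norm = 0, L_norm = L / L_rand, SW = 0,
                          connected = connected,
                          density = attr(graph, "density")),
                     class = "small_world_metrics"))
  }
  structure(list(C = C, L = L, C_rand = C_rand, L_rand = L_rand,
                 C_norm = C / C_rand, L_norm = L / L_rand,
                 SW = (C / C_rand) / (L / L_rand),
                 connected = connected,
                 density = attr(graph, "density")),
            class = "small_world_metrics")
}

#' @export
print.small_world_metrics <- function(x, ...) {
  cat(sprintf("<small_world_metrics> C = %.4f, L = %.4f, C/Crand = %.4f, L/Lrand = %.4f, SW = %.4f%s\n",
              x$C, x$L, x$C_norm, x$L_norm, x$SW,
              if (isTRUE(x$connected)) "" else " (disconnected)"))
  invisible(x)
}

#' Erdos-Renyi random binary graph
#'
#' Each of the `n(n-1)/2` node pairs is included independently with
#' probability `p`.
#'
#' @param n number of nodes (`>= 2`).
#' @param p edge probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return A `binary_graph`.
#' @export
erdos_renyi <- function(n, p, seed = NULL) {
  stopifnot(n >= 2, p >= 0, p <= 1)
  adj <- matrix(0L, n, n)
  draw <- with_seed(seed, runif(n * (n - 1) / 2))
  adj[upper.tri(adj)] <- as.integer(draw < p)
  adj <- adj + t(adj)
  structure(adj, class = c("binary_graph", "matrix", "array"),
            density = p, n_edges = sum(adj) / 2L)
}

#' Small-world metrics across a density grid
#'
#' Thresholds one connectivity matrix at each requested density and computes
#' [small_worldness()] for every resulting graph. The default grid is 10% to
#' 50% in steps of 5% (9 densities). By construction the edge set at a lower
#' density is a subset of the edge set at any higher density.
#'
#' @param m symmetric connectivity matrix.
#' @param densities strictly increasing vector of densities in `(0, 1]`.
#' @param n_null,n_swap_factor null-model settings passed to
#'   [small_worldness()].
#' @param seed optional integer seed.
#' @return A data.frame with one row per density: columns `density`, `C`,
#'   `L`, `C_rand`, `L_rand`, `SW`, `connected`.
#' @export
density_sweep <- function(m, densities = seq(0.10, 0.50, by = 0.05),
                          n_null = 10, n_swap_factor = 10, seed = NULL) {
  if (any(diff(densities) <= 0)) stop("densities must be strictly increasing")
  rows <- lapply(seq_along(densities), function(i) {
    g <- threshold_by_density(m, densities[i])
    sw <- small_worldness(g, n_null, n_swap_factor, child_seed(seed, i))
    data.frame(density = densities[i], C = sw$C, L = sw$L,
               C_rand = sw$C_rand, L_rand = sw$L_rand, SW = sw$SW,
               connected = sw$connected)
  })
  do.call(rbind, rows)
}
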