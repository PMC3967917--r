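# Independent oracles used to check the package implementations.
# These deliberately use brute-force formulations, not the package's code.

# Pearson correlation of endpoint degrees over the directed edge list.
oracle_assortativity <- function(g) {
  k <- igraph::degree(g)
  e <- igraph::as_edgelist(g, names = FALSE)
  ka <- c(k[e[, 1]], k[e[, 2]])
  kb <- c(k[e[, 2]], k[e[, 1]])
  suppressWarnings(stats::cor(ka, kb))
}

# Local clustering by exhaustive triangle enumeration.
oracle_clustering <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (x in seq_len(k - 1)) for (y in (x + 1):k)
      tri <- tri + a[nb[x], nb[y]]
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

# Modularity by the direct double sum over all ordered node pairs.
oracle_modularity <- function(g, membership, resolution = 1) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  k <- igraph::degree(g)
  m <- igraph::ecount(g)
  q <- 0
  n <- nrow(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j])
      q <- q + a[i, j] - resolution * k[i] * k[j] / (2 * m)
  }
  q / (2 * m)
}

# Mean path length and diameter by BFS from every node.
oracle_paths <- function(g) {
  d <- igraph::distances(g)   # BFS per source on unweighted graphs
  ut <- d[upper.tri(d)]
  ut <- ut[is.finite(ut)]
  list(mean_path = mean(ut), diameter = max(ut))
}

# Exact minimum number of boxes of topological diameter < l covering the
# graph, by backtracking over box assignments (small graphs only).
oracle_min_boxes <- function(g, l_b) {
  d <- igraph::distances(g)
  n <- nrow(d)
  if (l_b == 1) return(n)
  ok <- d < l_b
  assign_nodes <- function(node, boxes) {
    if (node > n) return(length(boxes))
    best <- Inf
    for (b in seq_along(boxes)) {
      if (all(ok[node, boxes[[b]]])) {
        boxes2 <- boxes
        boxes2[[b]] <- c(boxes2[[b]], node)
        best <- min(best, assign_nodes(node + 1, boxes2))
      }
    }
    # open a new box (prune: never beats current best bound implicitly)
    best <- min(best, assign_nodes(node + 1, c(boxes, list(node))))
    best
  }
  assign_nodes(2, list(1L))
}

# An Erdos-Renyi test graph; m clamped to the feasible range.
random_test_graph <- function(n, m) {
  igraph::sample_gnm(n, min(m, n * (n - 1) / 2))
}

# Edge set as a canonical sorted character vector, for equality checks.
edge_key <- function(g) {
  e <- igraph::as_edgelist(g, names = FALSE)
  sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "-"))
}

# Mean Euclidean length of a graph's edges under given coordinates.
mean_edge_length <- function(g, coords) {
  e <- igraph::as_edgelist(g, names = FALSE)
  mean(sqrt(rowSums((coords[e[, 1], , drop = FALSE] -
                     coords[e[, 2], , drop = FALSE])^2)))
}

# Uniform random coordinates in a brain-scale box.
coords_box <- function(n, seed = 1) {
  set.seed(seed)
  cbind(x = runif(n, 0, 140), y = runif(n, 0, 170), z = runif(n, 0, 110))
}
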