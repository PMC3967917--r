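#' @importFrom stats cor cov optim quantile rbinom rnorm runif sd setNames var
#' @importFrom utils combn head read.table write.table
NULL

## Internal: assert an igraph object, simple and undirected.
check_graph <- function(g, arg = "g") {
  if (!igraph::is_igraph(g))
    stop(sprintf("`%s` must be an igraph object", arg), call. = FALSE)
  if (igraph::is_directed(g))
    stop(sprintf("`%s` must be undirected", arg), call. = FALSE)
  invisible(g)
}

## Internal: edge matrix as 1-based integer endpoints, one row per edge.
edge_ends <- function(g) igraph::as_edgelist(g, names = FALSE)

#' Binarize a weighted connectivity matrix into a graph
#'
#' Builds the simple undirected graph whose edge \eqn{(i,j)} is present
#' whenever \eqn{W_{ij} > 0}, discarding all weight information. This is the
#' topological reduction applied to tractography connectivity matrices: an
#' edge records that any tract, of any strength, links the two regions.
#'
#' @param w A square, symmetric, nonnegative numeric matrix. Nonzero
#'   diagonal entries are ignored with a warning.
#' @return An igraph object with `nrow(w)` vertices.
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 0.2; w[2, 3] <- w[3, 2] <- 5
#' g <- binarize(w)
#' igraph::ecount(g)  # 2
#' @export
binarize <- function(w) {
  if (!is.matrix(w) || !is.numeric(w))
    stop("`w` must be a numeric matrix", call. = FALSE)
  if (nrow(w) != ncol(w))
    stop(sprintf("`w` must be square, got %d x %d", nrow(w), ncol(w)),
         call. = FALSE)
  asym <- which(w != t(w), arr.ind = TRUE)
  if (nrow(asym) > 0) {
    i <- asym[1, 1]; j <- asym[1, 2]
    stop(sprintf("`w` is not symmetric: w[%d,%d]=%g but w[%d,%d]=%g",
                 i, j, w[i, j], j, i, w[j, i]), call. = FALSE)
  }
  if (any(diag(w) != 0))
    warning("nonzero diagonal entries ignored")
  a <- (w > 0) * 1
  diag(a) <- 0
  igraph::graph_from_adjacency_matrix(a, mode = "undirected", diag = FALSE)
}

#' Degree distribution summary
#'
#' Tabulates the degree distribution and reports the mode degree(s) with
#' their node count, the degree range, the mean degree \eqn{2M/N}, and the
#' connection density \eqn{2M/(N(N-1))}.
#'
#' @param g An undirected igraph object.
#' @return An object of class `degree_stats`: a list with `distribution`
#'   (named integer vector, degree -> node count), `mode_degree`,
#'   `mode_count`, `min_degree`, `max_degree`, `mean_degree`, `density`.
#' @export
degree_stats <- function(g) {
  check_graph(g)
  n <- igraph::vcount(g)
  if (n < 1) stop("graph has no nodes", call. = FALSE)
  k <- igraph::degree(g)
  tab <- table(k)
  dist <- setNames(as.integer(tab), names(tab))
  mx <- max(dist)
  modes <- as.integer(names(dist)[dist == mx])
  out <- list(
    distribution = dist,
    mode_degree = modes,
    mode_count = mx,
    min_degree = min(k),
    max_degree = max(k),
    mean_degree = 2 * igraph::ecount(g) / n,
    density = if (n > 1) 2 * igraph::ecount(g) / (n * (n - 1)) else 0
  )
  class(out) <- "degree_stats"
  out
}

#' @export
print.degree_stats <- function(x, ...) {
  cat("Degree distribution summary\n")
  cat(sprintf("  mode degree: %s (%d nodes)\n",
              paste(x$mode_degree, collapse = " & "), x$mode_count))
  cat(sprintf("  range: %d-%d   mean: %.3f   density: %.4f\n",
              x$min_degree, x$max_degree, x$mean_degree, x$density))
  invisible(x)
}

#' Degree assortativity
#'
#' Pearson correlation between the degrees of the nodes at either end of an
#' edge, computed over the directed edge list (each edge counted in both
#' orientations). Positive values mean high-degree nodes preferentially
#' attach to other high-degree nodes.
#'
#' @param g An undirected igraph object with at least one edge.
#' @return A single number in \eqn{[-1, 1]}, or `NA` (with a warning) when
#'   the endpoint-degree variance is zero, as for regular graphs where the
#'   correlation is undefined.
#' @export
assortativity_coef <- function(g) {
  check_graph(g)
  if (igraph::ecount(g) < 1) stop("graph has no edges", call. = FALSE)
  k <- igraph::degree(g)
  e <- edge_ends(g)
  ka <- c(k[e[, 1]], k[e[, 2]])
  kb <- c(k[e[, 2]], k[e[, 1]])
  if (var(ka) == 0 || var(kb) == 0) {
    warning("endpoint degrees have zero variance; assortativity undefined")
    return(NA_real_)
  }
  cor(ka, kb)
}

#' Per-node degree, neighbor degree, and clustering profile
#'
#' For every node computes its degree \eqn{k_i}, the mean degree of its
#' neighbors \eqn{k^{nn}_i} (the scatter behind assortativity), and the
#' local clustering coefficient \eqn{C_i = 2 T_i / (k_i (k_i - 1))}, where
#' \eqn{T_i} is the number of triangles through the node and the
#' denominator counts node triples containing it. \eqn{C_i} is set to 0
#' for nodes of degree below 2; \eqn{k^{nn}_i} is `NA` for isolated nodes.
#'
#' @param g An undirected igraph object.
#' @return An object of class `node_profile`: a data frame with columns
#'   `node` (0-based id), `degree`, `knn`, `clustering`, plus attribute
#'   `global_clustering`, the mean of `clustering` over all nodes.
#' @export
node_profile <- function(g) {
  check_graph(g)
  k <- igraph::degree(g)
  ci <- igraph::transitivity(g, type = "local", isolates = "zero")
  ci[k < 2] <- 0
  knn <- rep(NA_real_, length(k))
  if (igraph::ecount(g) > 0) {
    kn <- suppressWarnings(igraph::knn(g))$knn
    knn[k >= 1] <- kn[k >= 1]
  }
  out <- data.frame(node = seq_along(k) - 1L, degree = k,
                    knn = knn, clustering = ci, row.names = NULL)
  attr(out, "global_clustering") <- mean(ci)
  class(out) <- c("node_profile", "data.frame")
  out
}

#' Global clustering coefficient
#'
#' Mean of the local clustering coefficients over all nodes (nodes of
#' degree below 2 contribute 0).
#'
#' @param g An undirected igraph object.
#' @return A number in \eqn{[0, 1]}.
#' @export
global_clustering <- function(g) {
  attr(node_profile(g), "global_clustering")
}

## Internal: ordinary least squares of log10(y) on log10(x).
## Returns a power_fit with `exponent` equal to the slope.
power_fit <- function(x, y, negate = FALSE) {
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("fewer than 2 positive points for log-log fit",
                          call. = FALSE)
  lx <- log10(x); ly <- log10(y)
  if (var(lx) == 0) {
    if (var(ly) == 0) {
      # single support point (e.g. a regular graph with uniform
      # clustering): any slope fits; report 0 by convention
      out <- list(exponent = 0, slope = 0, intercept = mean(ly),
                  r_squared = 1, points_used = data.frame(x = x, y = y))
      class(out) <- "power_fit"
      return(out)
    }
    stop("degenerate fit: all x identical", call. = FALSE)
  }
  slope <- cov(lx, ly) / var(lx)
  intercept <- mean(ly) - slope * mean(lx)
  res <- ly - (intercept + slope * lx)
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst < 1e-300) 1 else 1 - sum(res^2) / sst
  out <- list(exponent = if (negate) -slope else slope,
              slope = slope, intercept = intercept,
              r_squared = r2,
              points_used = data.frame(x = x, y = y))
  class(out) <- "power_fit"
  out
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: exponent %.4f (R^2 = %.3f, %d points)\n",
              x$exponent, x$r_squared, nrow(x$points_used)))
  invisible(x)
}

#' Network hierarchy exponent
#'
#' Fits the presumed power law \eqn{C_i \propto k_i^{-\beta}} between local
#' clustering and degree; the fitted \eqn{\beta} is the network hierarchy.
#' Nodes with \eqn{k_i \ge 2} and \eqn{C_i > 0} enter an ordinary
#' least-squares fit on base-10 logs, one point per node (no binning).
#'
#' @param profile A `node_profile`, or an igraph object (profiled first).
#' @return A `power_fit` whose `exponent` is \eqn{\beta} (negated log-log
#'   slope); `points_used` records the included \eqn{(k_i, C_i)} pairs.
#' @export
hierarchy_exponent <- function(profile) {
  if (igraph::is_igraph(profile)) profile <- node_profile(profile)
  use <- profile$degree >= 2 & profile$clustering > 0
  if (sum(use) < 3)
    stop("hierarchy fit needs at least 3 nodes with degree >= 2 and positive clustering",
         call. = FALSE)
  power_fit(profile$degree[use], profile$clustering[use], negate = TRUE)
}

#' Shortest-path metrics
#'
#' Mean shortest path length \eqn{P}, diameter \eqn{D}, and the fraction of
#' nodes in the largest connected component. Path metrics are computed by
#' breadth-first search over all node pairs of the largest component, so
#' that graphs with isolated nodes (empirical parcellations routinely have
#' them) still yield finite values; `component_fraction` reports how much
#' of the network that covers.
#'
#' @param g An undirected igraph object with at least 2 nodes and 1 edge.
#' @return A list with `mean_path` (average over unordered reachable
#'   pairs), `diameter`, and `component_fraction`.
#' @export
path_metrics <- function(g) {
  check_graph(g)
  if (igraph::vcount(g) < 2) stop("need at least 2 nodes", call. = FALSE)
  if (igraph::ecount(g) < 1) stop("graph has no edges", call. = FALSE)
  comp <- igraph::components(g)
  frac <- max(comp$csize) / igraph::vcount(g)
  if (frac < 1)
    message(sprintf("path metrics on largest component (%.1f%% of nodes)",
                    100 * frac))
  sub <- largest_component(g)
  d <- igraph::distances(sub)
  ut <- d[upper.tri(d)]
  list(mean_path = mean(ut), diameter = max(ut), component_fraction = frac)
}

## Internal: induced subgraph on the largest connected component.
largest_component <- function(g) {
  comp <- igraph::components(g)
  if (comp$no == 1) return(g)
  keep <- which(comp$membership == which.max(comp$csize))
  igraph::induced_subgraph(g, keep)
}
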