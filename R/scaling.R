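#' Greedy box covering of a network
#'
#' Covers the network with the fewest possible boxes such that every pair
#' of nodes sharing a box lies at topological (shortest-path) distance
#' strictly less than `l_b`. Uses the standard greedy-coloring realization
#' of box counting: nodes are visited in a random order and each is placed
#' in the first existing box whose members are all within distance
#' `l_b - 1`, or opens a new box. `l_b = 1` forces singleton boxes;
#' `l_b > D` (diameter) allows a single box.
#'
#' @param g A connected undirected igraph object; on disconnected input the
#'   largest component is used with a message.
#' @param l_b Positive integer box size.
#' @param dist Optional precomputed shortest-path distance matrix.
#' @return The number of boxes \eqn{N_B} (integer).
#' @export
box_cover <- function(g, l_b, dist = NULL) {
  check_graph(g)
  if (l_b < 1) stop("`l_b` must be >= 1", call. = FALSE)
  if (is.null(dist)) {
    comp <- igraph::components(g)
    if (comp$no > 1) {
      message("box covering on largest connected component")
      g <- largest_component(g)
    }
    dist <- igraph::distances(g)
  }
  greedy_cover(dist, l_b, sample.int(nrow(dist)))
}

## Internal: greedy box cover for one node order.
## dmax[u, b] tracks the max distance from u to current members of box b.
greedy_cover <- function(dist, l_b, ord) {
  n <- nrow(dist)
  if (l_b == 1) return(n)
  dmax <- matrix(0, n, 0)
  nb <- 0L
  for (u in ord) {
    placed <- FALSE
    if (nb > 0) {
      fits <- which(dmax[u, seq_len(nb)] < l_b)
      if (length(fits) > 0) {
        b <- fits[1]
        dmax[, b] <- pmax(dmax[, b], dist[, u])
        placed <- TRUE
      }
    }
    if (!placed) {
      nb <- nb + 1L
      dmax <- cbind(dmax, dist[, u])
    }
  }
  nb
}

#' Topological fractal dimension by box counting
#'
#' Estimates the exponent \eqn{d_B} of \eqn{N_B \propto l_B^{-d_B}}, where
#' \eqn{N_B} is the number of boxes of topological size \eqn{l_B} needed to
#' cover the network. The tiling is non-deterministic, so box counts are
#' averaged over `tilings` random node orders (50 by default); within a
#' tiling the count at each scale is the best cover found at any smaller
#' scale too, since such covers remain valid. The log-log fit includes
#' scales with \eqn{l_B \ge 3} (falling back to 2 on small-diameter
#' graphs) and \eqn{2 \le N_B < N}, excluding the forced endpoints
#' \eqn{N_B(1) = N} and \eqn{N_B(l_B > D) = 1} and the most
#' discreteness-biased smallest scale.
#'
#' @param g An undirected igraph object; the largest component is used.
#' @param tilings Number of random tilings to average over.
#' @return An object of class `scaling_curve` with `points` (data frame of
#'   scale, mean count, sd), `fit` (a `power_fit`; `exponent` is
#'   \eqn{d_B}), and `kind = "box_counting"`. Networks whose diameter is
#'   too small to give two usable scales raise an error.
#' @export
fractal_dimension <- function(g, tilings = 50) {
  check_graph(g)
  g <- largest_component(g)
  n <- igraph::vcount(g)
  dist <- igraph::distances(g)
  diam <- max(dist)
  if (diam < 3)
    warning("diameter below 3; fractal dimension estimate is unreliable")
  scales <- 1:(diam + 1)
  counts <- matrix(NA_real_, length(scales), tilings)
  for (t in seq_len(tilings)) {
    ord <- sample.int(n)
    raw <- vapply(scales, function(l) greedy_cover(dist, l, ord),
                  numeric(1))
    # a valid cover at scale l is valid at any larger scale, so the best
    # known count is non-increasing; enforce that feasibility bound
    counts[, t] <- cummin(raw)
  }
  mean_nb <- rowMeans(counts)
  sd_nb <- apply(counts, 1, sd)
  pts <- data.frame(scale = scales, count = mean_nb, sd = sd_nb)
  # the smallest box size carries the strongest finite-size bias (a box
  # of diameter < 2 is a clique; the discreteness correction scales as
  # (l+1)/l), so the fit starts at l_B = 3 when enough scales exist
  use <- scales >= 3 & mean_nb >= 2 & mean_nb < n
  if (sum(use) < 2) use <- scales >= 2 & mean_nb >= 2 & mean_nb < n
  if (sum(use) < 2)
    stop("diameter too small: fewer than 2 usable scale points for the box-counting fit",
         call. = FALSE)
  fit <- power_fit(pts$scale[use], pts$count[use], negate = TRUE)
  out <- list(points = pts, fit = fit, kind = "box_counting",
              tilings = tilings, n_nodes = n, diameter = diam)
  class(out) <- "scaling_curve"
  out
}

#' @export
print.scaling_curve <- function(x, ...) {
  lab <- switch(x$kind, box_counting = "d_B", rentian = "p_T", "exponent")
  cat(sprintf("Scaling curve (%s): %s = %.3f (R^2 = %.3f, %d scales)\n",
              x$kind, lab, x$fit$exponent, x$fit$r_squared,
              nrow(x$fit$points_used)))
  invisible(x)
}

#' Recursive min-cut bisection
#'
#' Recursively halves the node set (part sizes differing by at most one)
#' while heuristically minimizing the number of cut edges, recording for
#' every partition at every level the number of nodes inside, `n`, and its
#' boundary edge count `e`: the edges of the subgraph being bisected with
#' exactly one endpoint inside the partition (the min-cut value of the
#' bisection step). Splitting stops when a further split would produce
#' parts smaller than `min_part`. The bisection heuristic is spectral
#' (Fiedler vector median split) refined by Kernighan-Lin balanced swap
#' passes, ignoring any spatial node positions.
#'
#' @param g An undirected igraph object with at least `2 * min_part` nodes.
#' @param min_part Smallest part size worth splitting into; default 8.
#' @return A data frame with columns `level`, `n`, `e`, one row per
#'   partition produced at any level of the recursion.
#' @export
recursive_bisection <- function(g, min_part = 8) {
  check_graph(g)
  n <- igraph::vcount(g)
  if (n < 2 * min_part)
    stop(sprintf("need at least %d nodes", 2 * min_part), call. = FALSE)
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  rows <- list()
  recurse <- function(nodes, level) {
    halves <- bisect_nodes(nodes, adj)
    h1 <- halves[[1]]
    in1 <- logical(n)
    in1[h1] <- TRUE
    innodes <- logical(n)
    innodes[nodes] <- TRUE
    # cut edges of this bisection step: one endpoint in each half
    cut <- sum(vapply(h1, function(u) {
      nb <- adj[[u]]
      sum(innodes[nb] & !in1[nb])
    }, numeric(1)))
    for (h in halves)
      rows[[length(rows) + 1]] <<- data.frame(level = level,
                                              n = length(h), e = cut)
    for (h in halves)
      if (length(h) >= 2 * min_part) recurse(h, level + 1)
  }
  recurse(seq_len(n), 1L)
  do.call(rbind, rows)
}

## Internal: split `nodes` into two balanced halves with few cut edges.
## Spectral split on the induced subgraph, then KL-style refinement.
bisect_nodes <- function(nodes, adj) {
  nn <- length(nodes)
  idx <- integer(length(adj))
  idx[nodes] <- seq_len(nn)
  # induced adjacency lists in local indices
  ladj <- lapply(nodes, function(u) {
    nb <- adj[[u]]
    idx[nb[nb %in% nodes]]
  })
  deg <- lengths(ladj)
  side <- spectral_split(ladj, deg, nn)
  side <- kl_refine(ladj, side)
  list(nodes[side], nodes[!side])
}

## Fiedler-vector median split; random balanced split as fallback.
spectral_split <- function(ladj, deg, nn) {
  n1 <- ceiling(nn / 2)
  if (sum(deg) == 0) {
    side <- logical(nn); side[sample.int(nn, n1)] <- TRUE
    return(side)
  }
  lap <- diag(deg)
  for (u in seq_len(nn)) lap[u, ladj[[u]]] <- lap[u, ladj[[u]]] - 1
  ev <- eigen(lap, symmetric = TRUE)
  f <- ev$vectors[, nn - 1]
  # ties (e.g. disconnected subgraphs) broken by random jitter rank
  ord <- order(f, sample.int(nn))
  side <- logical(nn)
  side[ord[seq_len(n1)]] <- TRUE
  side
}

## Kernighan-Lin refinement: full passes of tentative locked swaps with
## best-prefix rollback, repeated until a pass yields no net gain.
kl_refine <- function(ladj, side, max_passes = 10, cand = 8) {
  nn <- length(side)
  gain_of <- function(u) {
    nb <- ladj[[u]]
    sum(side[nb] != side[u]) - sum(side[nb] == side[u])
  }
  for (pass in seq_len(max_passes)) {
    gain <- vapply(seq_len(nn), gain_of, numeric(1))
    locked <- logical(nn)
    swaps <- matrix(0L, 0, 2)
    gains <- numeric(0)
    nsteps <- min(sum(side), sum(!side))
    for (step in seq_len(nsteps)) {
      a <- which(side & !locked)
      b <- which(!side & !locked)
      if (length(a) == 0 || length(b) == 0) break
      a <- a[order(gain[a], decreasing = TRUE)]
      a <- a[seq_len(min(cand, length(a)))]
      b <- b[order(gain[b], decreasing = TRUE)]
      b <- b[seq_len(min(cand, length(b)))]
      best <- c(-Inf, 0L, 0L)
      for (u in a) for (v in b) {
        gg <- gain[u] + gain[v] - 2 * (v %in% ladj[[u]])
        if (gg > best[1]) best <- c(gg, u, v)
      }
      u <- best[2]; v <- best[3]
      # tentatively swap u and v, lock them, update neighbor gains
      for (w in ladj[[u]]) gain[w] <- gain[w] +
          if (side[w] == side[u]) 2 else -2
      side[u] <- !side[u]
      for (w in ladj[[v]]) gain[w] <- gain[w] +
          if (side[w] == side[v]) 2 else -2
      side[v] <- !side[v]
      gain[u] <- -gain[u] + 2 * (v %in% ladj[[u]])
      gain[v] <- -gain[v] + 2 * (u %in% ladj[[v]])
      locked[u] <- TRUE; locked[v] <- TRUE
      swaps <- rbind(swaps, c(u, v))
      gains <- c(gains, best[1])
    }
    if (length(gains) == 0) break
    cum <- cumsum(gains)
    kbest <- which.max(cum)
    if (cum[kbest] <= 0) kbest <- 0
    # roll back swaps beyond the best prefix
    if (kbest < nrow(swaps)) {
      for (s in seq(nrow(swaps), kbest + 1)) {
        side[swaps[s, 1]] <- !side[swaps[s, 1]]
        side[swaps[s, 2]] <- !side[swaps[s, 2]]
      }
    }
    if (kbest == 0 || cum[kbest] == 0) break
  }
  side
}

#' Topological Rent exponent from a bisection curve
#'
#' Fits \eqn{e \propto n^{p_T}} over the recorded partitions: the slope of
#' log boundary-crossing edges versus log partition size is the
#' topological Rent exponent. Partitions with `e = 0` are excluded (and an
#' all-zero curve is an error); values of \eqn{p_T} outside \eqn{(0, 1)}
#' are flagged with a warning since physical networks are expected inside
#' that range.
#'
#' @param curve Data frame with columns `n` and `e`, as returned by
#'   [recursive_bisection()].
#' @param n_min,n_max Optional inclusion window on partition size; both
#'   default to no restriction.
#' @return A `power_fit` whose `exponent` is \eqn{p_T}.
#' @export
rent_exponent <- function(curve, n_min = -Inf, n_max = Inf) {
  if (all(curve$e == 0)) stop("all partitions have zero boundary edges",
                              call. = FALSE)
  use <- curve$e > 0 & curve$n >= n_min & curve$n <= n_max
  if (sum(use) < 3)
    stop("need at least 3 partitions with boundary edges in the fit window",
         call. = FALSE)
  x <- curve$n[use]; y <- curve$e[use]
  if (var(log10(y)) == 0) {
    # saturated boundary counts: slope exactly 0
    fit <- list(exponent = 0, slope = 0, intercept = log10(y[1]),
                r_squared = 1, points_used = data.frame(x = x, y = y))
    class(fit) <- "power_fit"
    return(fit)
  }
  fit <- power_fit(x, y)
  if (fit$exponent <= 0 || fit$exponent >= 1)
    warning(sprintf("Rent exponent %.3f outside (0, 1)", fit$exponent))
  fit
}

#' Topological Rentian scaling of a network
#'
#' Convenience pipeline: [recursive_bisection()] followed by
#' [rent_exponent()] with partitions of at least `min_part` nodes included
#' in the fit (smaller fragments are dominated by discreteness).
#'
#' @inheritParams recursive_bisection
#' @return An object of class `scaling_curve` with `kind = "rentian"`;
#'   `points` holds the (n, e) pairs and `fit$exponent` is \eqn{p_T}.
#' @export
rentian_scaling <- function(g, min_part = 8) {
  curve <- recursive_bisection(g, min_part = min_part)
  fit <- rent_exponent(curve, n_min = min_part)
  out <- list(points = data.frame(scale = curve$n, count = curve$e,
                                  sd = NA_real_),
              curve = curve, fit = fit, kind = "rentian",
              n_nodes = igraph::vcount(g), min_part = min_part)
  class(out) <- "scaling_curve"
  out
}

#' Serialize a scaling curve to TSV plus a JSON fit block
#'
#' Writes the (scale, mean count, sd) table as TSV and the fitted exponent,
#' intercept and R-squared as a JSON sidecar (`<path>.fit.json`).
#'
#' @param curve A `scaling_curve`.
#' @param path Output TSV path.
#' @export
write_scaling_curve <- function(curve, path) {
  write.table(curve$points, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  fit <- list(kind = curve$kind, exponent = curve$fit$exponent,
              intercept = curve$fit$intercept,
              r_squared = curve$fit$r_squared)
  jsonlite::write_json(fit, paste0(path, ".fit.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
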