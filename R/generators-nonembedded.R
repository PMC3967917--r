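## Non-embedded synthetic network models. All generators return a simple
## undirected igraph with exactly `n` nodes and exactly `m` edges, and all
## draw their randomness from R's global RNG (use set.seed() for
## reproducibility).

max_edges <- function(n) n * (n - 1) / 2

check_nm <- function(n, m) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (m < 0 || m > max_edges(n))
    stop(sprintf("`m` must be in [0, %d] for n = %d", max_edges(n), n),
         call. = FALSE)
}

## Internal: linear index of pair (i < j) among all unordered pairs,
## and its inverse. Pairs are enumerated column-major: (1,2),(1,3),(2,3),...
pair_index_to_edge <- function(idx, n) {
  j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
  # guard against floating-point overshoot at exact triangular numbers
  over <- (j - 1) * (j - 2) / 2 >= idx
  j[over] <- j[over] - 1
  i <- idx - (j - 1) * (j - 2) / 2
  cbind(i, j)
}

edges_to_graph <- function(pairs, n) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(pairs) > 0) g <- igraph::add_edges(g, t(pairs))
  g
}

#' Erdos-Renyi random graph with fixed edge count
#'
#' The G(N, M) benchmark: `m` edges placed uniformly at random among all
#' node pairs. The degree distribution is sharply peaked, with variance
#' approximately equal to the mean degree.
#'
#' @param n Number of nodes.
#' @param m Number of edges, at most `n (n - 1) / 2`.
#' @return An igraph object with exactly `n` nodes and `m` edges.
#' @export
gen_er <- function(n, m) {
  check_nm(n, m)
  igraph::sample_gnm(n, m)
}

#' Configuration-model randomization by double edge swaps
#'
#' Degree-preserving rewiring: repeatedly picks two existing edges
#' uniformly at random and switches their endpoints, rejecting swaps that
#' would create self-loops or duplicate edges. The degree sequence of the
#' input is preserved exactly while all other structure is randomized.
#'
#' @param g A simple undirected igraph object.
#' @param n_swaps Number of attempted swaps; default `10 * ecount(g)`.
#' @return A simple igraph object with the same degree sequence as `g`.
#' @export
gen_cf <- function(g, n_swaps = 10 * igraph::ecount(g)) {
  check_graph(g)
  if (igraph::ecount(g) < 2) return(g)
  igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps))
}

#' Ring lattice with random remainder edges
#'
#' Each node is joined to its `floor(m/n)` nearest neighbors on either
#' side of a ring (a symmetric band of base degree `2 * floor(m/n)`); the
#' remaining `m - n * floor(m/n)` edges are placed uniformly at random
#' among unused pairs.
#'
#' @param n Number of nodes.
#' @param m Number of edges; must be at least `n` so the band is defined.
#' @return An igraph object with exactly `n` nodes and `m` edges.
#' @export
gen_rl <- function(n, m) {
  check_nm(n, m)
  if (m < n) stop("`m` must be >= `n` for the ring-lattice band",
                  call. = FALSE)
  half <- m %/% n
  if (2 * half >= n)
    stop("band width too large: need floor(m/n) < n/2", call. = FALSE)
  i <- rep(seq_len(n), each = half)
  off <- rep(seq_len(half), times = n)
  j <- ((i - 1 + off) %% n) + 1
  band <- cbind(pmin(i, j), pmax(i, j))
  g <- edges_to_graph(band, n)
  extra <- m - igraph::ecount(g)
  if (extra > 0) g <- add_random_edges(g, extra)
  g
}

## Internal: add `extra` edges uniformly at random among absent pairs.
add_random_edges <- function(g, extra) {
  n <- igraph::vcount(g)
  have <- edge_ends(g)
  have_idx <- pair_to_index(have[, 1], have[, 2])
  free <- setdiff(seq_len(max_edges(n)), have_idx)
  if (length(free) < extra) stop("not enough free pairs", call. = FALSE)
  pick <- free[sample.int(length(free), extra)]
  igraph::add_edges(g, t(pair_index_to_edge(pick, n)))
}

pair_to_index <- function(i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (hi - 1) * (hi - 2) / 2 + lo
}

#' Gaussian drop-off model
#'
#' Connection weight between nodes `i < j` decays as a Gaussian in their
#' index offset, \eqn{w(i, j) = \exp(-(j - i)^2 / (2 \kappa^2))}
#' (non-periodic), emulating an adjacency matrix whose edge density drops
#' off at rate \eqn{\kappa} away from the diagonal. Exactly `m` pairs are
#' drawn by weighted sampling without replacement so all models share an
#' identical edge count.
#'
#' @param n Number of nodes.
#' @param m Number of edges.
#' @param kappa Band width \eqn{\kappa > 0} of the Gaussian drop-off.
#' @return An igraph object with exactly `n` nodes and `m` edges.
#' @export
gen_gd <- function(n, m, kappa) {
  check_nm(n, m)
  if (kappa <= 0) stop("`kappa` must be > 0", call. = FALSE)
  idx <- seq_len(max_edges(n))
  ends <- pair_index_to_edge(idx, n)
  w <- exp(-((ends[, 2] - ends[, 1])^2) / (2 * kappa^2))
  pick <- sample.int(length(idx), m, prob = w)
  edges_to_graph(ends[pick, , drop = FALSE], n)
}

#' Fit the Gaussian band width of an adjacency matrix
#'
#' Reorders the graph with a bandwidth-reducing permutation (spectral
#' envelope reduction: nodes sorted by their Fiedler-vector coordinate,
#' component-wise), computes the edge density of each off-diagonal of the
#' reordered adjacency matrix, and least-squares fits a Gaussian
#' \eqn{a \exp(-d^2 / (2 \kappa^2))} to the density profile over the first
#' `max_offset` off-diagonals.
#'
#' @param g An undirected igraph object.
#' @param max_offset Number of off-diagonals used; default 400 (clamped to
#'   `n - 1`).
#' @return A list with `kappa`, `amplitude`, `r_squared`, and `profile`
#'   (data frame of offset and density).
#' @export
fit_band_kappa <- function(g, max_offset = 400) {
  check_graph(g)
  n <- igraph::vcount(g)
  ord <- spectral_order(g)
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  e <- edge_ends(g)
  d <- abs(pos[e[, 1]] - pos[e[, 2]])
  kmax <- min(max_offset, n - 1)
  cnt <- tabulate(d[d <= kmax], nbins = kmax)
  dens <- cnt / (n - seq_len(kmax))
  off <- seq_len(kmax)
  sse <- function(p) {
    a <- p[1]; kap <- p[2]
    if (a <= 0 || kap <= 0) return(1e10)
    sum((dens - a * exp(-off^2 / (2 * kap^2)))^2)
  }
  k0 <- sqrt(sum(off^2 * dens) / max(sum(dens), 1e-12))
  fit <- optim(c(max(dens), k0), sse, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  pred <- fit$par[1] * exp(-off^2 / (2 * fit$par[2]^2))
  sst <- sum((dens - mean(dens))^2)
  list(kappa = fit$par[2], amplitude = fit$par[1],
       r_squared = 1 - sum((dens - pred)^2) / sst,
       profile = data.frame(offset = off, density = dens))
}

## Internal: spectral envelope-reduction ordering. Components are laid
## out largest first; within a component nodes are sorted by their
## Fiedler-vector coordinate, which recovers band structure.
spectral_order <- function(g) {
  comp <- igraph::components(g)
  out <- integer(0)
  for (c_id in order(comp$csize, decreasing = TRUE)) {
    mem <- which(comp$membership == c_id)
    if (length(mem) <= 2) {
      out <- c(out, mem)
      next
    }
    sub <- igraph::induced_subgraph(g, mem)
    lap <- diag(igraph::degree(sub)) -
      as.matrix(igraph::as_adjacency_matrix(sub))
    ev <- eigen(lap, symmetric = TRUE)
    f <- ev$vectors[, length(mem) - 1]
    out <- c(out, mem[order(f)])
  }
  out
}

#' Modular small-world model
#'
#' Fully connected modules of `module_size` nodes (default 4; remainder
#' nodes form one smaller clique), randomly linked with one another by
#' enough uniformly placed inter-module edges to reach `m` edges total.
#'
#' @param n Number of nodes.
#' @param m Number of edges; at least the total intra-module edge count.
#' @param module_size Module size; default 4.
#' @return An igraph object with exactly `n` nodes and `m` edges.
#' @export
gen_ms <- function(n, m, module_size = 4) {
  check_nm(n, m)
  module <- rep(seq_len(ceiling(n / module_size)),
                each = module_size)[seq_len(n)]
  intra <- list()
  for (b in unique(module)) {
    mem <- which(module == b)
    if (length(mem) >= 2) intra[[length(intra) + 1]] <- t(combn(mem, 2))
  }
  intra <- do.call(rbind, intra)
  if (m < nrow(intra))
    stop(sprintf("`m` must be >= %d intra-module edges", nrow(intra)),
         call. = FALSE)
  g <- edges_to_graph(intra, n)
  extra <- m - nrow(intra)
  if (extra > 0) {
    # uniform among pairs in distinct modules (all non-intra pairs)
    g <- add_random_edges(g, extra)
  }
  g
}

#' Fractal hierarchical model
#'
#' Builds a 1024-node network of 4-node cliques paired over 8 hierarchical
#' levels: cross-pair edges between two level-`l` blocks are included
#' independently with probability \eqn{p_l = \min(1, \rho^l)}, a geometric
#' probability drop-off ladder (the modules themselves are complete,
#' \eqn{p_0 = 1}). `1024 - n` nodes are then deleted uniformly at random.
#' The drop-off rate \eqn{\rho} is adjusted by bisection over repeated
#' regenerations until the edge count matches `m`; if the discrete search
#' cannot hit `m` exactly, the closest realization is trimmed or topped up
#' by uniformly random edge removal/addition (warning if that adjustment
#' exceeds 0.5% of `m`).
#'
#' @param n Number of nodes, at most 1024.
#' @param m Number of edges.
#' @param max_iter Bisection iterations over \eqn{\rho}; default 30.
#' @return An igraph object with exactly `n` nodes and `m` edges.
#' @export
gen_fh <- function(n, m, max_iter = 30) {
  if (n > 1024) stop("`n` must be <= 1024", call. = FALSE)
  check_nm(n, m)
  keep <- sort(sample.int(1024, n))
  build <- function(rho) fh_realize(rho, keep)
  lo <- 0; hi <- 1
  best <- NULL; best_gap <- Inf
  for (it in seq_len(max_iter)) {
    rho <- (lo + hi) / 2
    pairs <- build(rho)
    gap <- nrow(pairs) - m
    if (abs(gap) < best_gap) {
      best <- pairs; best_gap <- abs(gap)
    }
    if (gap == 0) break
    if (gap > 0) hi <- rho else lo <- rho
  }
  if (best_gap > 0.005 * m)
    warning(sprintf("edge-count adjustment of %d edges (%.2f%% of m)",
                    best_gap, 100 * best_gap / m))
  g <- edges_to_graph(best, n)
  gap <- igraph::ecount(g) - m
  if (gap > 0) {
    drop <- sample.int(igraph::ecount(g), gap)
    g <- igraph::delete_edges(g, drop)
  } else if (gap < 0) {
    g <- add_random_edges(g, -gap)
  }
  g
}

## Internal: one FH realization. Returns a 2-column pair matrix in the
## retained nodes' final (1..n) labels. Cross-block edges are drawn by
## binomial counts per block pair, then sampled as distinct cross pairs.
fh_realize <- function(rho, keep) {
  full <- 1024L
  present <- logical(full)
  present[keep] <- TRUE
  newid <- integer(full)
  newid[keep] <- seq_along(keep)
  pairs <- list()
  # level 0: 4-node cliques
  for (b in seq_len(full / 4)) {
    mem <- keep[keep > (b - 1) * 4 & keep <= b * 4]
    if (length(mem) >= 2)
      pairs[[length(pairs) + 1]] <- t(combn(newid[mem], 2))
  }
  for (l in 1:8) {
    bs <- 4 * 2^(l - 1)               # block size at this level
    p_l <- min(1, rho^l)
    if (p_l <= 0) next
    nblocks <- full / bs
    for (bp in seq_len(nblocks / 2)) {
      a0 <- (2 * bp - 2) * bs
      left <- keep[keep > a0 & keep <= a0 + bs]
      right <- keep[keep > a0 + bs & keep <= a0 + 2 * bs]
      npairs <- length(left) * length(right)
      if (npairs == 0) next
      cnt <- rbinom(1, npairs, p_l)
      if (cnt == 0) next
      pick <- sample.int(npairs, cnt)
      i <- ((pick - 1) %% length(left)) + 1
      j <- ((pick - 1) %/% length(left)) + 1
      pairs[[length(pairs) + 1]] <- cbind(newid[left[i]], newid[right[j]])
    }
  }
  do.call(rbind, pairs)
}

#' Barabasi-Albert growth with tunable attachment exponent
#'
#' Starts from a single edge connecting two nodes and adds one node at a
#' time, wiring it to `m_t` distinct existing nodes chosen with
#' probability proportional to \eqn{k^\gamma}. Per-node edge budgets
#' alternate between `floor` and `ceiling` of the average so the final
#' edge count is exactly `m`. As \eqn{\gamma \to 0} attachment becomes
#' uniform and the graph approaches Erdos-Renyi.
#'
#' @param n Number of nodes (at least 3).
#' @param m Number of edges; at least `n - 1` so the graph stays connected.
#' @param gamma Attachment exponent \eqn{\gamma \ge 0}; default 1
#'   (classical linear preferential attachment).
#' @return An igraph object with exactly `n` nodes and `m` edges.
#' @export
gen_ba <- function(n, m, gamma = 1) {
  check_nm(n, m)
  if (gamma < 0) stop("`gamma` must be >= 0", call. = FALSE)
  if (n < 3) stop("`n` must be >= 3", call. = FALSE)
  if (m < n - 1) stop("`m` must be >= n - 1", call. = FALSE)
  # per-node budgets: m - 1 edges over nodes 3..n, as even as possible,
  # capped by the number of existing nodes at arrival
  total <- m - 1
  quota <- rep(total %/% (n - 2), n - 2)
  r <- total %% (n - 2)
  if (r > 0) {
    bump <- unique(round(seq(1, n - 2, length.out = r)))
    extra_r <- r - length(bump)
    quota[bump] <- quota[bump] + 1
    if (extra_r > 0)   # collisions from rounding: give the rest to the end
      quota[seq(n - 2, by = -1, length.out = extra_r)] <-
        quota[seq(n - 2, by = -1, length.out = extra_r)] + 1
  }
  cap <- pmin(quota, seq(2, n - 1))
  excess <- sum(quota - cap)
  t <- n - 2
  while (excess > 0 && t >= 1) {       # push capped excess to latest nodes
    room <- (t + 1) - cap[t]
    add <- min(room, excess)
    cap[t] <- cap[t] + add
    excess <- excess - add
    t <- t - 1
  }
  if (excess > 0) stop("`m` too large for growth schedule", call. = FALSE)
  k <- numeric(n)
  k[1:2] <- 1
  ei <- integer(m); ej <- integer(m)
  ei[1] <- 1L; ej[1] <- 2L
  ne <- 1L
  for (t in 3:n) {
    mt <- cap[t - 2]
    if (mt == 0) next
    existing <- seq_len(t - 1)
    w <- k[existing]^gamma
    if (all(w == 0)) w <- rep(1, length(existing))
    tgt <- existing[sample.int(length(existing), mt, prob = w)]
    ei[ne + seq_len(mt)] <- t
    ej[ne + seq_len(mt)] <- tgt
    ne <- ne + mt
    k[t] <- k[t] + mt
    k[tgt] <- k[tgt] + 1
  }
  edges_to_graph(cbind(ei[seq_len(ne)], ej[seq_len(ne)]), n)
}

#' Affinity growth model
#'
#' A two-step preferential attachment growth designed to hard-code degree
#' assortativity and hierarchy. Each node carries a fixed latent affinity
#' \eqn{a_i} drawn uniformly in \eqn{[0, 1]}. After `m0` uniform seed
#' edges, edges are grown one at a time: a source `i` is drawn from nodes
#' with spare capacity with probability proportional to \eqn{a_i^\gamma},
#' a candidate `j` is drawn uniformly, and the pair is accepted with
#' probability \eqn{\exp(-|a_i - a_j| / (\delta a_i^\epsilon))}; rejected
#' proposals are resampled. The acceptance width \eqn{\delta a_i^\epsilon}
#' grows with affinity, so low-affinity (hence low-degree) nodes are the
#' choosiest and cluster among similar-affinity partners, producing
#' positive assortativity. For the clustering-degree relation to decay
#' (hierarchy), the edge density inside an affinity band must fall with
#' affinity; that density scales as \eqn{a^{\gamma - \epsilon}}, so the
#' defaults take \eqn{\epsilon > \gamma}.
#'
#' @param n Number of nodes.
#' @param m Number of edges.
#' @param m0 Number of uniform seed edges, at most `m`; default `m %/% 10`.
#' @param gamma Source-selection exponent; default 1.
#' @param delta Base acceptance width; default 0.4.
#' @param epsilon Affinity exponent of the acceptance width; default 2
#'   (kept above `gamma` so clustering decays with degree).
#' @param max_proposals Safety cap on total proposals; default 1e7.
#' @return An igraph object with exactly `n` nodes and `m` edges, with the
#'   affinities stored in vertex attribute `affinity`.
#' @export
gen_af <- function(n, m, m0 = m %/% 10, gamma = 1, delta = 0.4,
                   epsilon = 2, max_proposals = 1e7) {
  check_nm(n, m)
  if (m0 > m || m0 < 0) stop("`m0` must be in [0, m]", call. = FALSE)
  if (gamma <= 0 || delta <= 0 || epsilon <= 0)
    stop("`gamma`, `delta`, `epsilon` must be > 0", call. = FALSE)
  a <- runif(n)
  adjmat <- matrix(FALSE, n, n)
  k <- integer(n)
  ei <- integer(m); ej <- integer(m)
  ne <- 0L
  add_edge <- function(i, j) {
    ne <<- ne + 1L
    ei[ne] <<- i; ej[ne] <<- j
    adjmat[i, j] <<- TRUE; adjmat[j, i] <<- TRUE
    k[i] <<- k[i] + 1L; k[j] <<- k[j] + 1L
  }
  if (m0 > 0) {
    seed <- pair_index_to_edge(sample.int(max_edges(n), m0), n)
    for (s in seq_len(m0)) add_edge(seed[s, 1], seed[s, 2])
  }
  wsrc <- a^gamma
  proposals <- 0
  while (ne < m) {
    proposals <- proposals + 1
    if (proposals > max_proposals)
      stop("affinity growth stalled: proposal budget exhausted",
           call. = FALSE)
    elig <- which(k < n - 1)
    i <- elig[sample.int(length(elig), 1, prob = wsrc[elig])]
    j <- sample.int(n, 1)
    if (j == i || adjmat[i, j]) next
    if (runif(1) < exp(-abs(a[i] - a[j]) / (delta * a[i]^epsilon)))
      add_edge(i, j)
  }
  g <- edges_to_graph(cbind(ei, ej), n)
  igraph::V(g)$affinity <- a
  g
}
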