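test_that("every non-embedded generator hits N and M exactly and is simple", {
  set.seed(1)
  base <- gen_er(60, 240)
  gens <- list(
    er = function() gen_er(60, 240),
    cf = function() gen_cf(base),
    rl = function() gen_rl(60, 240),
    gd = function() gen_gd(60, 240, kappa = 6),
    ms = function() gen_ms(60, 240),
    fh = function() suppressWarnings(gen_fh(60, 240)),
    ba = function() gen_ba(60, 240),
    af = function() gen_af(60, 240)
  )
  for (nm in names(gens)) {
    for (i in 1:5) {
      g <- gens[[nm]]()
      expect_equal(igraph::vcount(g), 60, label = nm)
      expect_equal(igraph::ecount(g), 240, label = nm)
      expect_true(igraph::is_simple(g), label = nm)
    }
  }
})

test_that("generators are bit-reproducible under a fixed seed", {
  for (gen in list(function() gen_er(40, 100),
                   function() gen_gd(40, 100, 5),
                   function() gen_ba(40, 100),
                   function() gen_af(40, 100),
                   function() suppressWarnings(gen_fh(40, 100)))) {
    set.seed(77); g1 <- gen()
    set.seed(77); g2 <- gen()
    expect_identical(edge_key(g1), edge_key(g2))
  }
})

test_that("configuration rewiring preserves the degree multiset exactly", {
  set.seed(2)
  g <- gen_ba(100, 300)
  rw <- gen_cf(g, n_swaps = 10 * 300)
  expect_equal(sort(igraph::degree(rw)), sort(igraph::degree(g)))
  expect_true(igraph::is_simple(rw))
  # a star admits no valid non-identity swap
  star <- igraph::make_star(4, mode = "undirected")
  expect_equal(sort(igraph::degree(gen_cf(star, 50))), c(1, 1, 1, 3))
})

test_that("ring lattice band yields the closed-form clustering", {
  g <- gen_rl(6, 6)
  expect_equal(sort(igraph::degree(g)), rep(2, 6))   # a cycle
  # k = 4 band: C_i = 3(k-2)/(4(k-1)) = 0.5 for every node
  set.seed(3)
  g2 <- gen_rl(20, 40)
  expect_equal(node_profile(g2)$clustering, rep(0.5, 20))
  set.seed(4)
  g3 <- gen_rl(5, 7)
  expect_equal(sum(igraph::degree(g3)), 14)
  expect_error(gen_rl(10, 9), "m")
})

test_that("Gaussian drop-off concentrates edges near the diagonal", {
  set.seed(5)
  g <- gen_gd(200, 600, kappa = 8)
  e <- igraph::as_edgelist(g, names = FALSE)
  expect_lt(mean(abs(e[, 1] - e[, 2])), 25)   # tight band
  # huge kappa approaches uniform offsets (ER-like)
  g2 <- gen_gd(200, 600, kappa = 1e6)
  e2 <- igraph::as_edgelist(g2, names = FALSE)
  expect_gt(mean(abs(e2[, 1] - e2[, 2])), 40)
  expect_error(gen_gd(10, 20, kappa = 0), "kappa")
})

test_that("band-width fitting recovers the generating kappa", {
  set.seed(6)
  g <- gen_gd(500, 3000, kappa = 30)
  fit <- fit_band_kappa(g)
  expect_equal(fit$kappa, 30, tolerance = 0.1)
  expect_gt(fit$r_squared, 0.8)
})

test_that("modular small-world is cliques plus inter-module edges", {
  g <- gen_ms(8, 12)
  expect_equal(igraph::components(g)$no, 2)      # two disjoint K4s
  expect_equal(sort(igraph::degree(g)), rep(3, 8))
  set.seed(7)
  g2 <- gen_ms(8, 13)
  expect_equal(sort(igraph::degree(g2)), c(3, 3, 3, 3, 3, 3, 4, 4))
  expect_error(gen_ms(8, 11), "intra-module")
  # remainder nodes form one smaller clique
  g3 <- gen_ms(10, 21)
  expect_equal(igraph::ecount(g3), 21)
})

test_that("fractal hierarchical realizations keep level-0 modules complete", {
  set.seed(8)
  keep <- sort(sample.int(1024, 200))
  pairs <- brainnull:::fh_realize(0.4, keep)
  g <- igraph::make_empty_graph(200, directed = FALSE)
  g <- igraph::add_edges(g, t(pairs))
  a <- igraph::as_adjacency_matrix(g)
  newid <- integer(1024); newid[keep] <- seq_along(keep)
  for (b in seq_len(256)) {
    mem <- newid[keep[keep > (b - 1) * 4 & keep <= b * 4]]
    if (length(mem) >= 2) {
      pairs_b <- t(combn(mem, 2))
      expect_true(all(a[pairs_b] > 0))
    }
  }
})

test_that("fractal hierarchical hits the exact edge count at brain-like scale", {
  set.seed(9)
  g <- suppressWarnings(gen_fh(998, 12000))
  expect_equal(igraph::vcount(g), 998)
  expect_equal(igraph::ecount(g), 12000)
})

test_that("preferential attachment produces trees and heavy tails", {
  set.seed(10)
  tree <- gen_ba(50, 49)
  expect_equal(igraph::ecount(tree), 49)
  expect_equal(igraph::components(tree)$no, 1)   # connected + M = N - 1
  expect_equal(igraph::ecount(tree), igraph::vcount(tree) - 1)

  # gamma = 0 (uniform attachment) yields smaller hubs than gamma = 1
  set.seed(11)
  mx0 <- replicate(15, max(igraph::degree(gen_ba(300, 600, gamma = 0))))
  mx1 <- replicate(15, max(igraph::degree(gen_ba(300, 600, gamma = 1))))
  expect_lt(suppressWarnings(wilcox.test(mx0, mx1, alternative = "less"))$p.value, 0.01)
})

test_that("linear preferential attachment has the classical degree exponent", {
  set.seed(12)
  g <- gen_ba(10000, 19997, gamma = 1)   # m = 2 per node
  k <- igraph::degree(g)
  kmin <- 5
  tail <- k[k >= kmin]
  alpha <- 1 + length(tail) / sum(log(tail / (kmin - 0.5)))
  expect_equal(alpha, 3, tolerance = 0.4 / 3)
})

test_that("affinity growth respects its contracts", {
  set.seed(13)
  g <- gen_af(80, 200, m0 = 40)
  expect_equal(igraph::ecount(g), 200)
  expect_true(igraph::is_simple(g))
  expect_length(igraph::V(g)$affinity, 80)
  # acceptance width is increasing in affinity: low-affinity nodes choosier
  a <- c(0.1, 0.5, 0.9)
  width <- 0.4 * a^2
  expect_true(all(diff(width) > 0))
  expect_error(gen_af(10, 20, gamma = -1), "gamma")
  # boundary: m0 = m places all edges uniformly, no growth loop
  set.seed(14)
  g2 <- gen_af(50, 100, m0 = 100)
  expect_equal(igraph::ecount(g2), 100)
})
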