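test_that("kernels evaluate to probabilities with the right shapes", {
  r <- seq(0, 100, by = 5)
  for (k in list(kernel_step(30), kernel_gaussian(20),
                 kernel_powerlaw(2, r_scale = 10, r_max = 80),
                 kernel_piecewise_powerlaw(1, 3, breakpoint = 30,
                                           r_scale = 10),
                 kernel_constant(0.4))) {
    g <- kernel_eval(k, r)
    expect_true(all(g >= 0 & g <= 1), label = k$form)
  }
  expect_equal(kernel_eval(kernel_step(30), c(10, 30, 31)), c(1, 1, 0))
  expect_equal(kernel_eval(kernel_powerlaw(2, r_scale = 10), 0), 1)
  # piecewise continuity at the breakpoint
  pw <- kernel_piecewise_powerlaw(1.5, 3, breakpoint = 40, r_scale = 10)
  eps <- 1e-9
  expect_equal(kernel_eval(pw, 40 - eps), kernel_eval(pw, 40 + eps),
               tolerance = 1e-6)
})

test_that("minimally wired connects the globally shortest pairs", {
  co <- cbind(x = c(0, 1, 2, 3), y = 0, z = 0)
  g3 <- gen_mw(co, 3)
  expect_setequal(edge_key(g3), c("1-2", "2-3", "3-4"))
  g5 <- gen_mw(co, 5)
  expect_setequal(edge_key(g5), c("1-2", "2-3", "3-4", "1-3", "2-4"))
  # deterministic
  co2 <- coords_box(60)
  expect_identical(edge_key(gen_mw(co2, 200)), edge_key(gen_mw(co2, 200)))
  # duplicate coordinates warn
  expect_warning(gen_mw(rbind(co, c(0, 0, 0)), 3), "duplicate")
})

test_that("random geometric graphs are assortative and shortest-biased", {
  set.seed(1)
  rg <- gen_rg(50, 50 * 49 / 2)
  expect_equal(igraph::ecount(rg$graph), 50 * 49 / 2)  # complete
  set.seed(2)
  for (i in 1:5) {
    rg <- gen_rg(200, 1500)
    mel <- mean_edge_length(rg$graph, rg$coords)
    pd <- as.matrix(dist(rg$coords))
    rand_mean <- mean(pd[upper.tri(pd)])
    expect_lt(mel, rand_mean)
  }
})

test_that("static drop-off with a step kernel reproduces minimal wiring", {
  co <- coords_box(120, seed = 3)
  pd <- sort(dist(co))
  m <- 400
  set.seed(4)
  gdd <- gen_dd(co, m, kernel_step(pd[m]))
  expect_identical(edge_key(gdd), edge_key(gen_mw(co, m)))
})

test_that("decreasing kernels shorten edges relative to uniform pairing", {
  co <- coords_box(150, seed = 5)
  pd <- as.matrix(dist(co))
  rand_mean <- mean(pd[upper.tri(pd)])
  set.seed(6)
  for (i in 1:5) {
    g <- gen_dd(co, 600, kernel_gaussian(40))
    expect_lt(mean_edge_length(g, co), rand_mean)
  }
  expect_error(gen_dd(co, 600, kernel_step(1)), "positive kernel weight")
})

test_that("drop-off growth yields exact M, no duplicates, wider degrees", {
  co <- coords_box(150, seed = 7)
  set.seed(8)
  g <- gen_ddg(co, 700, m0 = 70, kernel = kernel_gaussian(40))
  expect_equal(igraph::ecount(g), 700)
  expect_true(igraph::is_simple(g))
  expect_message(g0 <- gen_ddg(co, 300, m0 = 0,
                               kernel = kernel_gaussian(40)),
                 "seed edge")
  expect_equal(igraph::ecount(g0), 300)
  # growth broadens the degree distribution relative to static drop-off
  set.seed(9)
  width <- function(g) diff(range(igraph::degree(g)))
  w_dd <- replicate(10, width(gen_dd(co, 700, kernel_gaussian(40))))
  w_ddg <- replicate(10, width(gen_ddg(co, 700,
                                       kernel = kernel_gaussian(40))))
  expect_lt(suppressWarnings(wilcox.test(w_dd, w_ddg, alternative = "less"))$p.value, 0.05)
})

test_that("hybrid growth equals minimal wiring at the M0 = M boundary", {
  co <- coords_box(100, seed = 10)
  set.seed(11)
  g <- gen_hdg(co, 350, m0 = 350, kernel = kernel_gaussian(40))
  expect_identical(edge_key(g), edge_key(gen_mw(co, 350)))
})

test_that("mean edge length orders MW <= HDG <= DDG on shared coordinates", {
  co <- coords_box(150, seed = 12)
  kern <- kernel_gaussian(40)
  m <- 700
  set.seed(13)
  for (i in 1:5) {
    l_mw <- mean_edge_length(gen_mw(co, m), co)
    l_hdg <- mean_edge_length(gen_hdg(co, m, m0 = m %/% 2, kernel = kern),
                              co)
    l_ddg <- mean_edge_length(gen_ddg(co, m, m0 = m %/% 10,
                                      kernel = kern), co)
    expect_lte(l_mw, l_hdg)
    expect_lte(l_hdg, l_ddg + 1e-9)
  }
})

test_that("kernel fitting recovers a generating truncated power law", {
  co <- coords_box(400, seed = 14)
  kern <- kernel_powerlaw(2, r_scale = 15)
  set.seed(15)
  est <- replicate(5, {
    g <- gen_dd(co, 3000, kern)
    fit_distance_kernel(g, co, form = "single")$params$exponent
  })
  expect_equal(mean(est), 2, tolerance = 0.1)
})

test_that("kernel fitting is flat for distance-independent networks", {
  set.seed(16)
  slopes <- replicate(10, {
    co <- coords_box(200, seed = sample.int(1e6, 1))
    g <- gen_er(200, 2000)
    fit_distance_kernel(g, co, form = "single")$params$exponent
  })
  expect_lt(abs(mean(slopes)), 0.1)
})

test_that("hemisphere labels trigger separate intra/inter fits", {
  sur <- make_surrogate(200, 1500, "dd", seed = 17)
  fit <- fit_distance_kernel(sur$graph, sur$coords,
                             hemisphere = attr(sur$coords, "hemisphere"))
  expect_named(fit, c("intra", "inter"))
  expect_s3_class(fit$intra, "distance_kernel")
  expect_s3_class(fit$inter, "distance_kernel")
})
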