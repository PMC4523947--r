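make_toy_map <- function(idx, w, pre_dims) {
  structure(list(idx = idx, w = w, dist = matrix(0, nrow(idx), ncol(idx)),
                 pre_dims = pre_dims, post_dims = c(nrow(idx), 1),
                 n_conn = ncol(idx), radius = 1),
            class = "synaptic_map")
}

test_that("connectivity draws the configured number of distinct afferents", {
  m <- build_connectivity(c(64, 64, 8), c(8, 8), 201, 6, seed = 9)
  expect_equal(dim(m$idx), c(64, 201))
  expect_true(all(apply(m$idx, 1, function(r) !anyDuplicated(r))))
  # unit-norm initial weights
  expect_equal(sqrt(rowSums(m$w^2)), rep(1, 64), tolerance = 1e-12)
  # deterministic under seed
  m2 <- build_connectivity(c(64, 64, 8), c(8, 8), 201, 6, seed = 9)
  expect_identical(m$idx, m2$idx)
  expect_equal(m$w, m2$w)
  expect_error(build_connectivity(c(4, 4), c(2, 2), 50, 2), "exceeds")
})

test_that("the topological radius captures about 67% of realized connections", {
  # full-scale inter-layer geometry, >= 10^4 draws
  m <- build_connectivity(c(128, 128), c(10, 10), 100, 6, seed = 21)
  expect_equal(mean(m$dist <= m$radius), 0.67, tolerance = 0.03)
})

test_that("activation is the weighted linear sum of afferent rates", {
  map <- make_toy_map(matrix(c(1L, 2L), 1), matrix(c(0.6, 0.8), 1), c(2, 1))
  expect_equal(activate(map, c(0.5, 0.5)), 0.7)
  expect_equal(activate(map, c(0, 0)), 0)
  y <- c(0.3, 0.9)
  expect_equal(activate(map, 3 * y), 3 * activate(map, y))
  expect_error(activate(map, c(1, 2, 3)), "length")
})

test_that("the competitive lateral kernel sums to one and fixes uniform input", {
  sp <- lateral_spec("competitive", delta = 1.5, sigma = 1.38)
  k <- lateral_kernel(sp, c(16, 16))
  expect_equal(sum(k), 1, tolerance = 1e-12)
  u <- matrix(3.2, 16, 16)
  expect_equal(lateral_filter(u, sp), u, tolerance = 1e-9)
})

test_that("the SOM kernel is a difference of Gaussians with delta_E - delta_I at center", {
  sp <- lateral_spec("som", delta_E = 5.35, sigma_E = 1.4,
                     delta_I = 1.5, sigma_I = 2.76)
  k <- lateral_kernel(sp, c(16, 16))
  expect_equal(k[1, 1], 5.35 - 1.5)
  kc <- lateral_kernel(sp, c(17, 17), layout = "centered")
  expect_equal(kc[9, 9], 5.35 - 1.5)  # center lands mid-grid for odd dims
  # mexican hat: negative at mid-range distances
  expect_lt(k[1, 5], 0)
})

test_that("lateral filtering matches the direct convolution oracle", {
  set.seed(13)
  h <- matrix(rnorm(13 * 13), 13, 13)  # odd dims give a true kernel center
  for (sp in list(lateral_spec("competitive", sigma = 2, delta = 1.2),
                  lateral_spec("som"))) {
    kc <- lateral_kernel(sp, c(13, 13), layout = "centered")
    got <- lateral_filter(h, sp)
    ref <- oracle_conv_wrap(h, kc)
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("sigmoid transfer thresholds at the percentile and controls sparseness", {
  r <- seq(0, 1, length.out = 101)
  y <- sigmoid_transfer(r, percentile = 96, beta = 40)
  expect_equal(y[97], 0.5)  # r value equal to the threshold maps to 0.5
  expect_true(all(diff(y) > 0))
  set.seed(2)
  r <- rnorm(1e4)
  y <- sigmoid_transfer(r, percentile = 96, beta = 100)
  expect_equal(mean(y > 0.5), 0.04, tolerance = 0.01)
})

test_that("learning rules update weights as specified and keep unit norm", {
  set.seed(3)
  idx <- matrix(1:6, 2, 3)
  w <- matrix(runif(6), 2, 3); w <- w / sqrt(rowSums(w^2))
  map <- make_toy_map(idx, w, c(6, 1))
  pre <- runif(6)
  # hebb with zero post-rates: no change
  up <- learn_step(map, pre, c(0, 0), rule = "hebb", rate = 0.1)
  expect_equal(up$map$w, w)
  # hebb update direction and renormalization
  up <- learn_step(map, pre, c(1, 0.5), rule = "hebb", rate = 0.2)
  expect_equal(sqrt(rowSums(up$map$w^2)), c(1, 1), tolerance = 1e-9)
  raw <- w + 0.2 * c(1, 0.5) * matrix(pre[idx], 2, 3)
  expect_equal(up$map$w, raw / sqrt(rowSums(raw^2)), tolerance = 1e-12)
  # trace bookkeeping: from zero trace, eta = 0.8, y = 1 -> 0.2
  up <- learn_step(map, pre, c(1, 1), rule = "trace", rate = 0.1,
                   trace = NULL, eta = 0.8)
  expect_equal(up$trace, c(0.2, 0.2))
  # trace uses the PREVIOUS trace for the weight update: zero trace, no change
  expect_equal(up$map$w, w)
  # degenerate all-zero weights are an error
  map0 <- make_toy_map(idx, matrix(0, 2, 3), c(6, 1))
  expect_error(learn_step(map0, pre, c(0, 0), rule = "hebb"), "zero")
})

test_that("forward pass is deterministic and matches per-layer sparseness targets", {
  cfg <- network_preset("test_small")
  net <- build_network(cfg, seed = 4)
  sh <- enumerate_shapes(shape_family(3, 2))
  img <- render_shape(sh$shape[[3]], retina = 64)
  f1 <- forward_pass(net, img)
  f2 <- forward_pass(net, img)
  expect_identical(f1$top, f2$top)
  for (l in 1:3) {
    target <- (100 - cfg$layers[[l]]$sigmoid$percentile) / 100
    expect_lt(abs(mean(f1$layers[[l]]$y > 0.5) - target), 0.01)
    expect_true(all(f1$layers[[l]]$y >= 0 & f1$layers[[l]]$y <= 1))
  }
  expect_error(forward_pass(net, matrix(0, 32, 32)), "retina")
})

test_that("a translation-equivariant toy layer permutes rates under wrapped shifts", {
  # identity topology: each neuron reads exactly its own grid position
  idx <- matrix(seq_len(64), 64, 1)
  map <- make_toy_map(idx, matrix(1, 64, 1), c(8, 8))
  layer <- list(dims = c(8, 8), map = map,
                lateral = lateral_spec("competitive", sigma = 1.38),
                sigmoid = list(percentile = 88, beta = 75))
  layer$lat_kfft <- stats::fft(lateral_kernel(layer$lateral, c(8, 8)))
  set.seed(8)
  pre <- matrix(runif(64), 8, 8)
  y1 <- matrix(contournet:::layer_forward(layer, as.vector(pre))$y, 8, 8)
  y2 <- matrix(contournet:::layer_forward(layer,
                                          as.vector(wrap_shift(pre, 2, 3)))$y,
               8, 8)
  expect_equal(y2, wrap_shift(y1, 2, 3), tolerance = 1e-9)
})

test_that("training is deterministic, inert at k = 0, and settles over epochs", {
  sh <- enumerate_shapes(shape_family(3, 2))
  sq <- make_sequence(sh, retina = 64)
  net <- build_network(network_preset("test_small"), seed = 5)
  n0 <- train_network(net, sq, rule = "hebb", rate = 0, epochs = 2)
  for (l in 1:3) expect_equal(n0$layers[[l]]$map$w, net$layers[[l]]$map$w)
  na <- train_network(net, sq, rule = "hebb", epochs = 8)
  nb <- train_network(net, sq, rule = "hebb", epochs = 8)
  for (l in 1:3) expect_identical(na$layers[[l]]$map$w, nb$layers[[l]]$map$w)
  h <- attr(na, "history")
  # weight change declines as each layer converges
  for (l in 1:3) {
    hl <- h$mean_abs_dw[h$layer == l]
    expect_lt(mean(tail(hl, 3)), mean(head(hl, 3)))
  }
  # the simultaneous schedule trains every layer too
  ns <- train_network(net, sq, rule = "hebb", epochs = 3,
                      schedule = "simultaneous")
  for (l in 1:3) {
    expect_false(identical(ns$layers[[l]]$map$w, net$layers[[l]]$map$w))
  }
})

test_that("unit weight norms survive a full training run", {
  sh <- enumerate_shapes(shape_family(3, 2))
  sq <- make_sequence(sh, retina = 64)
  net <- train_network(build_network(network_preset("test_small"), seed = 6),
                       sq, rule = "trace", rate = 0.5, epochs = 3)
  for (l in 1:3) {
    expect_equal(sqrt(rowSums(net$layers[[l]]$map$w^2)),
                 rep(1, 1024), tolerance = 1e-9)
  }
})
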