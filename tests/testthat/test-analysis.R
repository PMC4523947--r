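perfect_cell_table <- function(fam = shape_family(3, 2), element = "s0:concave") {
  sh <- enumerate_shapes(fam)
  el <- element_table(sh)
  pos <- el$object_id[el$element == element]
  tibble::tibble(cell = 1L, object_id = sh$object_id,
                 rate = as.numeric(sh$object_id %in% pos))
}

test_that("a perfectly selective cell in a p = 2 design carries exactly one bit", {
  fam <- shape_family(3, 2)
  resp <- perfect_cell_table(fam)
  el <- element_table(enumerate_shapes(fam))
  info <- single_cell_information(resp, el)
  expect_equal(max(info$info), log2(2))
  expect_equal(info$info[info$element == "s0:concave"], 1.0)
})

test_that("a constant-rate cell carries zero information", {
  fam <- shape_family(3, 2)
  sh <- enumerate_shapes(fam)
  resp <- tibble::tibble(cell = 1L, object_id = sh$object_id, rate = 0.4)
  info <- single_cell_information(resp, element_table(sh))
  expect_true(all(abs(info$info) < 1e-12))
})

test_that("information matches the brute-force oracle to 1e-12 on random tables", {
  sh <- enumerate_shapes(shape_family(3, 2))
  el <- element_table(sh)
  for (seed in c(101, 202)) {
    resp <- tibble::as_tibble(random_response_table(5, sh, seed))
    got <- single_cell_information(resp, el)
    ref <- oracle_information(resp, el)
    merged <- merge(got, ref, by = c("cell", "element"))
    expect_equal(merged$info.x, merged$info.y, tolerance = 1e-12)
  }
})

test_that("selectivity counting applies the strict bands and matches the oracle", {
  fam <- shape_family(3, 2)
  sh <- enumerate_shapes(fam)
  el <- element_table(sh)
  resp <- perfect_cell_table(fam)
  counts <- count_selective_cells(resp, el)
  expect_equal(counts$n_selective[counts$element == "s0:concave"], 1L)
  expect_equal(sum(counts$n_selective), 1L)
  # a single sub-threshold positive response disqualifies the cell
  resp2 <- resp
  resp2$rate[resp2$rate == 1][1] <- 0.9991
  expect_equal(sum(count_selective_cells(resp2, el)$n_selective), 0L)
  # random tables against the double-loop oracle
  for (seed in c(31, 32)) {
    rr <- tibble::as_tibble(random_response_table(6, sh, seed))
    # make some cells cleanly selective
    pos <- el$object_id[el$element == "s1:convex"]
    rr$rate[rr$cell == 2] <- as.numeric(rr$object_id[rr$cell == 2] %in% pos)
    got <- count_selective_cells(rr, el)
    ref <- oracle_selective(rr, el)
    expect_equal(setNames(got$n_selective, got$element), ref)
  }
})

test_that("receptive-field backtracing multiplies weights along paths", {
  # two stacked 1-neuron layers over a single-filter retina
  net <- build_network(network_preset("test_small"), seed = 1)
  net$layers <- lapply(net$layers[1:2], function(l) l)
  net$layers[[1]]$map$idx <- matrix(1L, 1024, 1)
  net$layers[[1]]$map$w <- matrix(0.5, 1024, 1)
  net$layers[[2]]$map$idx <- matrix(1L, 1024, 1)
  net$layers[[2]]$map$w <- matrix(0.4, 1024, 1)
  rf <- backtrace_receptive_field(net, cell = 1, layer = 2)
  expect_equal(rf[1, 1, 1], 0.5 * 0.4)
  expect_equal(sum(rf != 0), 1)
  expect_true(all(rf >= 0))
  net$layers[[2]]$map$w[] <- 0
  expect_true(all(backtrace_receptive_field(net, 1, 2) == 0))
  expect_error(backtrace_receptive_field(net, 5000, 2), "out of range")
})

test_that("boundary segmentation finds one segment on a circle and n on a polygon", {
  phi <- seq(0, 2 * pi, length.out = 401)
  circle <- cbind(32 + 10 * cos(phi), 32 - 10 * sin(phi))
  segs <- segment_boundary(circle)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$curvature, 1 / 10, tolerance = 0.01)
  # straight-sided square: 4 segments ~90 degrees apart, ~zero curvature
  fam <- shape_family(4, 3)
  sq_spec <- shape_spec(fam, rep("straight", 4))
  ct <- shape_contour(sq_spec, radius = 20, center = c(32, 32))
  segs <- segment_boundary(ct)
  expect_equal(nrow(segs), 4L)
  expect_true(all(abs(segs$curvature) < 0.02))
  gaps <- sort(diff(sort(segs$angle)))
  expect_true(all(abs(gaps - 90) < 10))
})

test_that("segment angular positions rotate with the shape", {
  fam <- shape_family(4, 3)
  sp <- shape_spec(fam, c("convex", "straight", "concave", "straight"))
  s0 <- segment_boundary(shape_contour(sp, radius = 20, center = c(32, 32)))
  s90 <- segment_boundary(shape_contour(sp, radius = 20, center = c(32, 32),
                                        orientation = 90))
  expect_equal(nrow(s0), nrow(s90))
  rotated <- sort((s0$angle + 90) %% 360)
  expect_equal(sort(s90$angle), rotated, tolerance = 6)
})

test_that("tuning heatmaps average responses into the right bins", {
  # two objects x two orientations; one synthetic segment each
  segs <- tibble::tibble(
    object_id = c("a", "a", "b", "b"),
    orientation = c(0, 180, 0, 180),
    segment = 1L,
    curvature = c(0.09, 0.09, -0.09, -0.09),
    angle = c(70, 250, 70, 250),
    arc_frac = 1)
  resp <- tibble::tibble(cell = 1L,
                         object_id = rep(c("a", "b"), each = 2),
                         orientation = rep(c(0, 180), 2),
                         rate = c(1, 0.5, 0.2, 0))
  hm <- tuning_heatmap(resp, segs, curvature_bins = 4, angle_bins = 8,
                       curvature_range = c(-0.2, 0.2))
  # object a, orientation 0: curvature 0.1 at 70 deg -> bin (3, 2)
  expect_equal(hm$rate[hm$curv_bin == 3 & hm$angle_bin == 2], 1)
  expect_equal(hm$rate[hm$curv_bin == 3 & hm$angle_bin == 6], 0.5)
  expect_equal(hm$rate[hm$curv_bin == 2 & hm$angle_bin == 2], 0.2)
  expect_equal(sum(!is.na(hm$rate)), 4)
  expect_equal(sum(hm$n), 4)
  # permutation invariance over presentation order
  hm2 <- tuning_heatmap(resp[sample(4), ], segs, curvature_bins = 4,
                        angle_bins = 8, curvature_range = c(-0.2, 0.2))
  expect_equal(hm$rate, hm2$rate)
  # brute-force accumulation oracle over a random joined design
  set.seed(17)
  resp3 <- tidyr::expand_grid(cell = 1L, object_id = c("a", "b"),
                              orientation = c(0, 180))
  resp3$rate <- runif(4)
  hm3 <- tuning_heatmap(resp3, segs, curvature_bins = 4, angle_bins = 8,
                        curvature_range = c(-0.2, 0.2))
  for (i in which(!is.na(hm3$rate))) {
    cb <- attr(hm3, "curvature_breaks"); ab <- attr(hm3, "angle_breaks")
    sel <- segs$curvature > cb[hm3$curv_bin[i]] - 1e-9 &
      segs$curvature <= cb[hm3$curv_bin[i] + 1] + 1e-9 &
      segs$angle >= ab[hm3$angle_bin[i]] & segs$angle < ab[hm3$angle_bin[i] + 1]
    keys <- paste(segs$object_id[sel], segs$orientation[sel])
    ref <- mean(resp3$rate[paste(resp3$object_id, resp3$orientation) %in% keys])
    expect_equal(hm3$rate[i], ref)
  }
})

test_that("peak counting respects the 60% threshold, wrap, and plateaus", {
  g <- function(nr, nc) matrix(0, nr, nc)
  m <- g(8, 16)
  m[4, 5] <- 1; m[4, 4] <- 0.5; m[4, 6] <- 0.5  # single bump
  expect_equal(count_heatmap_peaks(m), 1L)
  m[7, 13] <- 1; m[7, 12] <- 0.4                # second, well separated
  expect_equal(count_heatmap_peaks(m), 2L)
  # flat heatmap: no strict local maxima
  expect_equal(count_heatmap_peaks(matrix(1, 8, 16)), 0L)
  # a local maximum below 60% of the heatmap mean is ignored
  m2 <- g(8, 16); m2[2, 2] <- 10; m2[6, 10] <- 0.04
  expect_equal(count_heatmap_peaks(m2, fraction = 0.6), 1L)
  # a two-cell plateau counts once
  m3 <- g(8, 16); m3[4, 5] <- 1; m3[4, 6] <- 1
  expect_equal(count_heatmap_peaks(m3), 1L)
  # wrap on the angle (column) axis: peak on the seam is one peak
  m4 <- g(8, 16); m4[4, 1] <- 1; m4[4, 16] <- 0.8
  expect_equal(count_heatmap_peaks(m4), 1L)
})

test_that("model-V4 correlation behaves like a Pearson correlation", {
  segs <- tidyr::expand_grid(object_id = "a", orientation = 0,
                             segment = 1:128)
  # build a heatmap directly: fill all bins from a model surface
  hm <- tuning_heatmap(
    tibble::tibble(cell = 1L, object_id = "a", orientation = 0, rate = 1),
    tibble::tibble(object_id = "a", orientation = 0, segment = 1L,
                   curvature = 0.1, angle = 70, arc_frac = 1),
    curvature_bins = 8, angle_bins = 16, curvature_range = c(-0.2, 0.2))
  model <- exp(-(((hm$curvature - 0.1)^2) / (2 * 0.05^2) +
                   (((hm$angle - 70 + 180) %% 360 - 180)^2) / (2 * 45^2)))
  hm$rate <- model
  expect_equal(v4_model_correlation(hm, 0.1, 70, c(0.05, 45)), 1.0)
  hm$rate <- -model
  expect_equal(v4_model_correlation(hm, 0.1, 70, c(0.05, 45)), -1.0)
  hm$rate <- 3 * model + 7
  expect_equal(v4_model_correlation(hm, 0.1, 70, c(0.05, 45)), 1.0)
  hm$rate <- rep(0.5, nrow(hm))
  expect_error(v4_model_correlation(hm, 0.1, 70), "variance")
})

test_that("feature maps score clustered max-information cells below the null", {
  # all max-info cells for one element packed into a 3x3 block
  cells_block <- as.vector(outer(2:4, (2:4 - 1) * 32, "+"))
  info <- tibble::tibble(
    cell = rep(1:1024, 2),
    element = rep(c("e1", "e2"), each = 1024),
    info = c(ifelse(1:1024 %in% cells_block, 1, 0), rep(0, 1024)))
  fm <- feature_map(info, c(32, 32), n_perm = 100, seed = 2)
  z1 <- fm$clustering_z[fm$element == "e1"]
  expect_lt(z1, -2)
  expect_lt(fm$mean_dist[fm$element == "e1"],
            fm$null_mean[fm$element == "e1"])
  # an element with no informative cells is flagged, not scored
  expect_true(is.na(fm$clustering_z[fm$element == "e2"]))
})
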