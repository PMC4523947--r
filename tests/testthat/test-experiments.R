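test_that("the capacity threshold matches brute-force pair counting", {
  expect_equal(capacity_threshold(4096), 91)
  expect_equal(capacity_threshold(1), 2)
  expect_equal(capacity_threshold(10), 5)
  brute <- function(N) {
    n <- 2
    while ((n + 1) * n / 2 <= N) n <- n + 1
    n
  }
  for (N in c(1, 2, 5, 17, 100, 1024, 4096, 20000)) {
    expect_equal(capacity_threshold(N), brute(N))
  }
})

test_that("a small study runs end to end with an untrained baseline", {
  cfg <- study_config(study = "study1", n_sides = 3, n_conformations = 2,
                      preset = "test_small", rule = "hebb", epochs = 3,
                      seed = 11)
  res <- run_study(cfg)
  expect_s3_class(res, "study_result")
  # six elements reported for 3 sides x 2 conformations
  expect_equal(nrow(res$selectivity$trained), 6)
  expect_equal(nrow(res$selectivity$untrained), 6)
  expect_false(is.null(res$responses$untrained))
  # tidiers summarize the run
  td <- tidy(res)
  expect_equal(nrow(td), 12)
  g <- glance(res)
  expect_equal(g$n_objects, 8)
  # identical config => identical result
  res2 <- run_study(cfg)
  expect_equal(res$responses$trained$rate, res2$responses$trained$rate)
  expect_identical(res$hash, res2$hash)
})

test_that("mirror testing aligns the reflected straight-right contour on the retina", {
  sh <- enumerate_shapes(shape_family(4, 3))
  net <- build_network(network_preset("test_small"), seed = 1)
  out <- run_mirror_test(net, sh)
  expect_equal(nrow(out$original), nrow(out$mirrored))
  # render one test object both ways: the vertical straight contour on the
  # right (side index 3, midpoint at 0 degrees) must occupy the same retinal
  # pixels after reflection
  keep <- vapply(sh$elements, function(e) e[4] == "straight", TRUE)
  sp <- sh$shape[keep][[1]]
  a <- render_shape(sp, retina = 64, radius = 0.15 * 64)
  m <- render_shape(sp, retina = 64, radius = 0.15 * 64, mirror = TRUE,
                    mirror_axis = out$axis)
  col <- round(out$axis) + 1
  band <- (col - 1):(col + 1)
  expect_true(sum(unclass(a)[, band] * unclass(m)[, band]) /
                sum(unclass(a)[, band]) > 0.9)
  # family without a straight conformation is rejected
  sh2 <- enumerate_shapes(shape_family(3, 2))
  expect_error(run_mirror_test(net, sh2), "straight")
})

test_that("hebb training increases the count of element-selective cells", {
  # scaled-down proof of principle: n = 3 sides, p = 2 conformations
  sh <- enumerate_shapes(shape_family(3, 2))
  el <- element_table(sh)
  sq <- make_sequence(sh, retina = 64)
  net <- build_network(network_preset("test_small"), seed = 1)
  trained <- train_network(net, sq, rule = "hebb", epochs = 10)
  n0 <- sum(count_selective_cells(response_table(net, sq), el)$n_selective)
  n1 <- sum(count_selective_cells(response_table(trained, sq), el)$n_selective)
  expect_gt(n1, n0)
})
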