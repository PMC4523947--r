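test_that("shape enumeration covers exactly p^n distinct objects in stable order", {
  cases <- list(c(3, 2, 8), c(4, 3, 81), c(3, 1, 1), c(5, 2, 32), c(4, 4, 256))
  for (cs in cases) {
    fam <- shape_family(cs[1], cs[2])
    sh <- enumerate_shapes(fam)
    expect_equal(nrow(sh), cs[3])
    expect_equal(anyDuplicated(sh$object_id), 0L)
  }
  # deterministic lexicographic order: first side varies slowest
  fam <- shape_family(3, 2)
  sh <- enumerate_shapes(fam)
  expect_equal(sh$elements[[1]], rep("concave", 3))
  expect_equal(sh$elements[[2]], c("concave", "concave", "convex"))
  expect_identical(sh$object_id, enumerate_shapes(fam)$object_id)
})

test_that("enumeration refuses families above the practical cap", {
  expect_error(enumerate_shapes(shape_family(6, 4)), "cap")
  expect_silent(enumerate_shapes(shape_family(6, 4), max_shapes = 5000))
})

test_that("a family exposes n*p boundary elements", {
  el <- element_table(enumerate_shapes(shape_family(4, 3)))
  expect_equal(length(unique(el$element)), 12)
  # every element appears in p^(n-1) objects
  expect_true(all(table(el$element) == 27))
})

test_that("rendering translates exactly with integer center shifts", {
  sp <- enumerate_shapes(shape_family(4, 3))$shape[[5]]
  a <- render_shape(sp, retina = 96, center = c(40, 48))
  b <- render_shape(sp, retina = 96, center = c(50, 48))
  # shift a right by 10 px and compare foreground
  shifted <- matrix(0, 96, 96)
  shifted[, 11:96] <- unclass(a)[, 1:86]
  expect_equal(shifted, unclass(b), ignore_attr = TRUE)
  expect_gt(sum(a > 0), 0)
})

test_that("mirrored rendering equals the horizontal flip about the midline", {
  sp <- enumerate_shapes(shape_family(3, 2))$shape[[2]]
  a <- render_shape(sp, retina = 64)
  m <- render_shape(sp, retina = 64, mirror = TRUE)
  expect_equal(unclass(m), unclass(a)[, 64:1], ignore_attr = TRUE)
})

test_that("shapes exceeding the retina raise an informative error", {
  sp <- enumerate_shapes(shape_family(3, 2))$shape[[1]]
  expect_error(render_shape(sp, retina = 64, center = c(60, 32)),
               "exceeds retina bounds")
})

test_that("filled rendering produces a solid silhouette containing the outline", {
  sp <- enumerate_shapes(shape_family(4, 3))$shape[[41]]
  o <- render_shape(sp, retina = 64)
  f <- render_shape(sp, retina = 64, fill = TRUE)
  expect_gt(sum(f), sum(o))
})

test_that("curvature-stimulus sets follow the vertex angle sum rule", {
  ps <- pasupathy_shapes(vertex_angle_sets = list(c(135, 135, 90)))
  expect_equal(nrow(ps), 5^3)
  expect_equal(length(unique(unlist(ps$elements))), 5)
  expect_error(pasupathy_shapes(vertex_angle_sets = list(c(120, 120, 90))),
               "360")
  # all contours closed
  for (i in c(1, 57, 125)) {
    ct <- shape_contour(ps$shape[[i]], radius = 20, center = c(32, 32))
    expect_lt(sqrt(sum((ct[1, ] - ct[nrow(ct), ])^2)), 1e-9)
  }
})

test_that("blob objects are deterministic under seed and smooth in curvature", {
  b1 <- blob_stimuli(10, retina = 64, seed = 3)
  b2 <- blob_stimuli(10, retina = 64, seed = 3)
  b3 <- blob_stimuli(10, retina = 64, seed = 4)
  expect_length(b1, 10)
  expect_identical(lapply(b1, unclass), lapply(b2, unclass))
  expect_false(identical(unclass(b1[[1]]), unclass(b3[[1]])))
  # curvature continuity: a smooth blob segments into a single piece
  segs <- segment_boundary(attr(b1[[1]], "contour"))
  expect_equal(nrow(segs), 1L)
})

test_that("presentation sequences sweep locations within an orientation within an object", {
  sh <- enumerate_shapes(shape_family(3, 2))
  sq <- make_sequence(sh, retina = 96, grid = c(2, 2), spacing = 10,
                      orientations = c(0, 90))
  fr <- sq$frames
  expect_equal(nrow(fr), 8 * 2 * 4)
  # object blocks are contiguous (no interleaving)
  expect_equal(sum(rle(fr$object_id)$values |> duplicated()), 0)
  # within an object, all locations of one orientation precede the next
  one <- fr[fr$object_id == fr$object_id[1], ]
  expect_equal(one$orientation, rep(c(0, 90), each = 4))
  expect_equal(one$location, rep(1:4, 2))
  # boundary flags exactly at object transitions
  expect_equal(which(fr$boundary), seq(1, nrow(fr), by = 8))
  # 3x3 grid gives nine locations
  sq9 <- make_sequence(sh[1:2, ], retina = 96, grid = c(3, 3), spacing = 10)
  expect_equal(max(sq9$frames$location), 9)
  # 10-degree orientation steps give 36 entries per location cycle
  sq36 <- make_sequence(sh[1, ], retina = 96,
                        orientations = seq(0, 350, by = 10))
  expect_equal(nrow(sq36$frames), 36)
})
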