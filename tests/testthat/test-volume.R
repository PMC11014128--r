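test_that("area-times-height tetrahedron volume matches the triple product", {
  # unit corner tetrahedron
  expect_equal(tetra_volume(c(1, 0, 1), c(0, 1, 1), c(0, 0, 1)), 1 / 6)

  # collinear base -> 0
  expect_equal(tetra_volume(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3)), 0)
  expect_equal(tetra_volume(c(1, 2, 3), c(1, 2, 3), c(5, 5, 5)), 0)

  set.seed(11)
  for (i in 1:1000) {
    v1 <- runif(3, -50, 50); v2 <- runif(3, -50, 50); v3 <- runif(3, -50, 50)
    got <- tetra_volume(v1, v2, v3)
    ref <- triple_volume(v1, v2, v3)
    expect_lt(abs(got - ref), 1e-9 * max(ref, 1e-12))
  }

  # vectorized form agrees with scalar calls
  V1 <- matrix(runif(30, -10, 10), 10)
  V2 <- matrix(runif(30, -10, 10), 10)
  V3 <- matrix(runif(30, -10, 10), 10)
  got <- tetra_volume(V1, V2, V3)
  for (i in 1:10)
    expect_equal(got[i], tetra_volume(V1[i, ], V2[i, ], V3[i, ]))
})

test_that("ROI triangulation covers exactly the interior unit squares", {
  roi <- matrix(TRUE, 2, 2)
  expect_equal(nrow(triangulate_roi(roi)), 2L)

  roi <- matrix(TRUE, 7, 11)
  expect_equal(nrow(triangulate_roi(roi)), 2L * 6L * 10L)

  # L-shaped ROI against per-square membership counting
  roi <- matrix(FALSE, 8, 8)
  roi[1:8, 1:3] <- TRUE
  roi[6:8, 1:8] <- TRUE
  tri <- triangulate_roi(roi)
  n_sq <- 0
  for (r in 1:7) for (c in 1:7)
    if (roi[r, c] && roi[r, c + 1] && roi[r + 1, c] && roi[r + 1, c + 1])
      n_sq <- n_sq + 1
  expect_equal(nrow(tri), 2L * n_sq)
  # all triangle vertices lie inside the ROI
  expect_true(all(roi[as.vector(tri)]))
  # deterministic
  expect_identical(tri, triangulate_roi(roi))

  # fewer than one full square -> empty triangulation, not an error
  tiny <- matrix(FALSE, 5, 5); tiny[2, 2:3] <- TRUE
  expect_equal(nrow(triangulate_roi(tiny)), 0L)
})

test_that("space volume of a constant-depth plane matches the closed form", {
  intr <- intr_small()
  set.seed(55)
  for (i in 1:10) {
    a <- sample(5:40, 1); b <- sample(5:30, 1)
    Z <- runif(1, 200, 1500)
    depth <- matrix(Z, intr$height, intr$width)
    roi <- matrix(FALSE, intr$height, intr$width)
    roi[3:(2 + b), 5:(4 + a)] <- TRUE
    got <- space_volume(depth, roi, intr)
    ref <- (a - 1) * (b - 1) * Z^3 / (3 * intr$f^2) / 1000
    expect_lt(abs(got$volume_cm3 - ref) / ref, 1e-6)
    expect_equal(got$n_tetrahedra, 2L * (a - 1L) * (b - 1L))
  }
})

test_that("degenerate ROIs yield zero volume", {
  intr <- intr_small()
  depth <- matrix(400, 60, 80)
  roi <- matrix(FALSE, 60, 80); roi[10, 10:11] <- TRUE  # 2 pixels
  res <- space_volume(depth, roi, intr)
  expect_equal(res$volume_cm3, 0)
  expect_equal(res$n_tetrahedra, 0L)
  expect_equal(res$n_skipped_px, 2L)
})

test_that("stepped and ragged surfaces match the brute-force integrator", {
  intr <- intr_small()
  # two-level step
  depth <- matrix(400, 60, 80)
  depth[10:30, 10:40] <- 360
  roi <- matrix(FALSE, 60, 80); roi[5:35, 5:45] <- TRUE
  got <- space_volume(depth, roi, intr)
  expect_equal(got$volume_cm3, brute_space_volume(depth, roi, intr),
               tolerance = 1e-12)

  # ragged random surface and ragged ROI
  set.seed(66)
  depth <- matrix(sample(300:500, 60 * 80, TRUE), 60, 80)
  roi <- matrix(runif(60 * 80) < 0.7, 60, 80)
  got <- space_volume(depth, roi, intr)
  expect_equal(got$volume_cm3, brute_space_volume(depth, roi, intr),
               tolerance = 1e-12)
})

test_that("space volume is monotone in depth", {
  intr <- intr_small()
  set.seed(77)
  for (i in 1:5) {
    d1 <- matrix(runif(60 * 80, 300, 450), 60, 80)
    d2 <- d1 + matrix(runif(60 * 80, 0, 40), 60, 80)  # farther everywhere
    roi <- disc_mask(60, 80, 30, 40, 18)
    expect_gte(space_volume(d2, roi, intr)$volume_cm3,
               space_volume(d1, roi, intr)$volume_cm3)
  }
})

test_that("intake estimation differences space volumes per food", {
  intr <- intr_small()
  depth <- matrix(400, 60, 80)
  labels <- matrix(0L, 60, 80)
  labels[10:25, 10:30] <- 1L
  labels[35:50, 40:70] <- 2L
  rois <- region_mask(labels, c("1" = "rice", "2" = "soup"))

  est <- estimate_intake(depth, depth, rois, intr)
  expect_equal(est$intake_cm3, c(0, 0))
  expect_equal(est$name, c("rice", "soup"))

  # removing a slab increases the post space volume by the slab volume
  pre <- depth; pre[10:25, 10:30] <- 380
  est <- estimate_intake(pre, depth, rois, intr)
  expect_gt(est$intake_cm3[1], 0)
  expect_equal(est$intake_cm3[2], 0)

  expect_warning(estimate_intake(depth, pre, rois, intr), "negative")
  expect_error(estimate_intake(depth, matrix(400, 10, 10), rois, intr),
               "dimensions")
})

test_that("single-object volume measures the silhouette shadow frustum", {
  # A lone object seen from above occupies its silhouette cone between its
  # top surface and the table: the camera cannot distinguish the object
  # from the space it obscures below its vertical walls, so the measured
  # volume is the frustum A/Zo^2 * (Zt^3 - Zo^3) / 3, not l*w*h. (That is
  # precisely why intake uses a pre/post difference, which cancels the
  # obscured part.)
  intr <- reference_intrinsics()
  sp <- scene_spec(intr, 400, solids = list(
    solid_cuboid("box", c(0, 0), 124, 126, 75)))
  sc <- render_scene(sp)
  bg <- render_scene(scene_spec(intr, 400))
  got <- object_volume(sc$depth, bg$depth, unclass(sc$mask), intr,
                       id = sc$region_ids[["box"]])
  frustum <- 124 * 126 / 325^2 * (400^3 - 325^3) / 3 / 1000
  expect_equal(got, frustum, tolerance = 0.015)

  # for a low flat slab the frustum and the true volume nearly coincide
  sp2 <- scene_spec(intr, 400, solids = list(
    solid_cuboid("slab", c(0, 0), 100, 100, 9)))
  sc2 <- render_scene(sp2)
  got2 <- object_volume(sc2$depth, bg$depth, unclass(sc2$mask), intr,
                        id = sc2$region_ids[["slab"]])
  expect_equal(got2, 90, tolerance = 0.03)
})
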