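test_that("an empty table renders to a constant depth plane", {
  intr <- intr_small()
  sc <- render_scene(scene_spec(intr, 400))
  expect_true(all(sc$depth == 400))
  expect_true(all(unclass(sc$mask) == 0))
})

test_that("analytic ground-truth volumes use the closed forms", {
  intr <- reference_intrinsics()
  # reference objects: cuboids l*w*h, cylinders pi*r^2*h, printed in cm^3
  sc <- render_scene(scene_spec(intr, 400, solids = list(
    solid_cuboid("a", c(0, 0), 124, 126, 75))))
  expect_equal(round(sc$volumes_cm3[["a"]], 2), 1171.80)

  sc <- render_scene(scene_spec(intr, 600, solids = list(
    solid_cylinder("d", c(0, 0), 46, 132))))
  expect_equal(round(sc$volumes_cm3[["d"]], 2), 877.48)

  sc <- render_scene(scene_spec(intr, 600, solids = list(
    solid_cylinder("e", c(0, 0), 66, 168))))
  expect_equal(round(sc$volumes_cm3[["e"]], 2), 2299.04)

  # bowl ground truth is the liquid volume
  sp <- scene_water_bowl(fill_mm = 20)
  sc <- render_scene(sp)
  expect_equal(sc$volumes_cm3[["water"]], 200)
})

test_that("rendering is perspective-correct", {
  intr <- reference_intrinsics()
  h_mm <- 80
  sc <- render_scene(scene_spec(intr, 400, solids = list(
    solid_cuboid("box", c(0, 0), 100, 60, h_mm))))
  d <- sc$depth

  # a flat-topped solid produces exactly two depth values when its walls
  # are invisible (camera above the solid's footprint)
  expect_setequal(unique(as.vector(d)), c(400, 400 - h_mm))

  # footprint width in pixels follows the pinhole model at the TOP depth,
  # not at the table depth (an orthographic stamp would get this wrong)
  top_cols <- range(which(colSums(d == 400 - h_mm) > 0))
  width_px <- diff(top_cols) + 1
  expect_lt(abs(width_px - 100 * intr$f / (400 - h_mm)), 2)
  expect_gt(abs(width_px - 100 * intr$f / 400), 10)

  # walls become visible for an off-center solid: depths between top and table
  sc2 <- render_scene(scene_spec(intr, 400, solids = list(
    solid_cuboid("box", c(80, 0), 100, 60, h_mm))))
  mids <- setdiff(unique(as.vector(sc2$depth)), c(400, 400 - h_mm))
  expect_true(length(mids) > 0)
  expect_true(all(mids > 400 - h_mm & mids < 400))
})

test_that("solids outside the frustum are rejected", {
  intr <- intr_small()
  expect_error(render_scene(scene_spec(intr, 400, solids = list(
    solid_cuboid("far", c(500, 0), 40, 40, 20)))), "frustum")
  # touching the border is also refused (its volume would be truncated)
  expect_error(render_scene(scene_spec(intr, 400, solids = list(
    solid_cuboid("edge", c(100, 0), 40, 40, 20)))), "border|frustum")
})

test_that("the noise model is seeded and recoverable by the temporal mode", {
  intr <- intr_small()
  sc <- render_scene(scene_spec(intr, 400, solids = list(
    solid_cuboid("box", c(0, 0), 60, 40, 30))))

  s1 <- apply_noise(sc$depth, noise_model(), n_frames = 10, seed = 5)
  s2 <- apply_noise(sc$depth, noise_model(), n_frames = 10, seed = 5)
  expect_identical(s1, s2)
  s3 <- apply_noise(sc$depth, noise_model(), n_frames = 10, seed = 6)
  expect_false(identical(s1, s3))

  # jitter stays within range; dropout only near edges
  delta <- abs(s1[[1]] - sc$depth)
  expect_lte(max(delta[s1[[1]] > 0]), 1)
  far_from_edge <- sc$depth == 400
  far_from_edge[, ] <- FALSE; far_from_edge[1:10, 1:10] <- TRUE
  expect_true(all(s1[[1]][far_from_edge] > 0))

  stack <- apply_noise(sc$depth, noise_model(), n_frames = 30, seed = 9)
  rec <- temporal_mode(stack)
  expect_gte(mean(rec == sc$depth), 0.999)
})

test_that("meal pairs carry exact analytic ground-truth intake", {
  pair <- make_meal_pair(scene_meal_tray(),
                         c(water = 37.5, side_dish = 21.25),
                         shift_px = c(8, -4), rotate_deg = 2)
  expect_equal(pair$true_intake_cm3[["water"]], 37.5, tolerance = 1e-12)
  expect_equal(pair$true_intake_cm3[["side_dish"]], 21.25, tolerance = 1e-12)

  # the plate (and its solids) moved: masks differ, same label sets
  expect_false(identical(unclass(pair$pre$mask), unclass(pair$post$mask)))
  expect_setequal(unique(as.vector(unclass(pair$post$mask))),
                  unique(as.vector(unclass(pair$pre$mask))))

  # requesting more than a food holds is an error
  expect_error(make_meal_pair(scene_meal_tray(), c(water = 1000)), "exceeds")
  # shifting a plateless scene is an error
  sp <- scene_spec(intr_small(), 400, solids = list(
    solid_cuboid("box", c(0, 0), 40, 30, 10)))
  expect_error(make_meal_pair(sp, c(box = 1), shift_px = c(5, 0)), "plate")
})

test_that("depth stacks round-trip through 16-bit PNG files", {
  intr <- intr_small()
  sc <- render_scene(scene_spec(intr, 400, solids = list(
    solid_cuboid("box", c(0, 0), 60, 40, 30))))
  stack <- apply_noise(sc$depth, noise_model(), n_frames = 3, seed = 2)
  dir <- file.path(tempdir(), "stack_rt")
  write_depth_stack(stack, dir)
  back <- read_depth_stack(dir)
  expect_equal(back, lapply(stack, `+`, 0))
  unlink(dir, recursive = TRUE)
})
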