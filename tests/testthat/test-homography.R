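test_that("special homographies come out exactly", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))

  H <- estimate_homography(sq, sq)
  expect_equal(unclass(H), diag(3), tolerance = 1e-12, ignore_attr = TRUE)

  Ht <- estimate_homography(sq, sq + cbind(rep(5, 4), rep(-3, 4)))
  expect_equal(unclass(Ht),
               rbind(c(1, 0, 5), c(0, 1, -3), c(0, 0, 1)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the fitted homography reproduces its defining correspondences", {
  set.seed(7)
  for (i in 1:25) {
    # random convex quadrilateral: jittered square corners
    src <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)) * 50 +
      matrix(runif(8, -8, 8), 4, 2)
    dst <- src + matrix(runif(8, -15, 15), 4, 2)
    H <- estimate_homography(src, dst)
    expect_lt(max(abs(apply_homography(H, src) - dst)), 1e-6)
    expect_gt(abs(det(unclass(H))), 0)
  }
})

test_that("degenerate correspondences are rejected", {
  src <- rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 5))  # three collinear
  expect_error(estimate_homography(src, src + 1), "degenerate|singular")
})

test_that("warping honors the sampling contract", {
  set.seed(21)
  img <- matrix(sample(100:500, 40 * 50, TRUE), 40, 50)

  Hid <- estimate_homography(rbind(c(0, 0), c(49, 0), c(49, 39), c(0, 39)),
                             rbind(c(0, 0), c(49, 0), c(49, 39), c(0, 39)))
  expect_equal(warp_image(img, Hid), img)

  # integer translation: values move, exposed border filled with 0
  src <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  Ht <- estimate_homography(src, src + cbind(rep(3, 4), rep(2, 4)))
  wt <- warp_image(img, Ht)
  expect_equal(wt[3:40, 4:50], img[1:38, 1:47])
  expect_true(all(wt[1:2, ] == 0))
  expect_true(all(wt[, 1:3] == 0))

  # round trip through a small rigid motion keeps >= 99% of interior pixels
  th <- 1 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 2.3), c(sin(th), cos(th), -1.7), c(0, 0, 1))
  corners <- rbind(c(0, 0), c(49, 0), c(49, 39), c(0, 39))
  Hr <- estimate_homography(corners, apply_homography(R, corners))
  Hb <- estimate_homography(apply_homography(R, corners), corners)
  back <- warp_image(warp_image(img, Hr), Hb)
  interior <- img[6:35, 6:45]
  expect_gte(mean(back[6:35, 6:45] == interior), 0.99)
})

test_that("rotating calipers finds minimum-area plate rectangles", {
  # axis-aligned rectangle is its own minimum-area rectangle
  m <- matrix(FALSE, 80, 120)
  m[11:70, 11:110] <- TRUE  # pixels (10..109, 10..69)
  corners <- find_plate_corners(m)
  expect_equal(corners,
               cbind(x = c(10, 109, 109, 10), y = c(10, 10, 69, 69)),
               ignore_attr = TRUE)

  # 45-degree diamond: vertices match a brute-force orientation sweep
  h <- 101; w <- 101
  xg <- matrix(rep(0:(w - 1), each = h), h, w)
  yg <- matrix(rep(0:(h - 1), times = w), h, w)
  diam <- abs(xg - 50) + abs(yg - 50) <= 30
  got <- find_plate_corners(diam)
  idx <- which(diam, arr.ind = TRUE)
  ref <- brute_min_rect(idx[, 2] - 1, idx[, 1] - 1)
  expect_lt(corner_dist(got, ref$corners), 0.5)

  # disc: any orientation, but side ~ diameter and area within 1%
  dm <- disc_mask(221, 221, 110, 110, 100)
  got <- find_plate_corners(dm)
  side1 <- sqrt(sum((got[2, ] - got[1, ])^2))
  side2 <- sqrt(sum((got[3, ] - got[2, ])^2))
  expect_lt(abs(side1 * side2 - 200^2) / 200^2, 0.01)
  idx <- which(dm, arr.ind = TRUE)
  ref <- brute_min_rect(idx[, 2] - 1, idx[, 1] - 1, step = 2e-3)
  expect_lt(abs(side1 * side2 - ref$area) / ref$area, 0.005)

  # degenerate masks
  expect_error(find_plate_corners(matrix(FALSE, 10, 10)), "degenerate")
  line <- matrix(FALSE, 10, 10); line[5, 2:9] <- TRUE
  expect_error(find_plate_corners(line), "degenerate|collinear")
})

test_that("corner ordering is clockwise from the image origin", {
  m <- matrix(FALSE, 60, 60)
  m[21:40, 11:50] <- TRUE
  corners <- find_plate_corners(m)
  expect_equal(corners[1, ], c(x = 10, y = 20))
  # clockwise on screen: next corner is to the right, then down, then left
  expect_equal(corners[2, ], c(x = 49, y = 20))
  expect_equal(corners[3, ], c(x = 49, y = 39))
  expect_equal(corners[4, ], c(x = 10, y = 39))
})

test_that("plate alignment registers a rigidly moved tray", {
  pair <- make_meal_pair(scene_meal_tray(),
                         c(water = 0, side_dish = 0),
                         shift_px = c(20, 10), rotate_deg = 5)
  pre_plate <- unclass(pair$pre$mask) == 1
  post_plate <- unclass(pair$post$mask) == 1
  al <- align_post_meal(pre_plate, post_plate,
                        post_masks = unclass(pair$post$mask))
  expect_gte(compute_iou(pre_plate, al$masks == 1), 0.98)
  expect_gt(abs(det(unclass(al$H))), 0)
})
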