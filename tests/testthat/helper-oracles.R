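# Shared fixtures and independent oracles for the test suite.

# Small camera for fast tests: 80x60 frame, optical center just off-center.
intr_small <- function() camera_intrinsics(150, 39.5, 29.5, 80, 60)

# Scalar-triple-product volume of the tetrahedron (origin, v1, v2, v3):
# the standard closed form, independent of the area-times-height route.
triple_volume <- function(v1, v2, v3) {
  abs(det(rbind(v1, v2, v3))) / 6
}

# Brute-force minimum-area enclosing rectangle: sweep a fine grid of
# orientations and take the smallest axis-aligned bounding box in the
# rotated frame. Returns area and the four vertices.
brute_min_rect <- function(px, py, step = 2e-4) {
  best <- NULL; best_area <- Inf
  for (th in seq(0, pi / 2, by = step)) {
    ct <- cos(th); st <- sin(th)
    u <- ct * px + st * py
    v <- -st * px + ct * py
    area <- diff(range(u)) * diff(range(v))
    if (area < best_area) {
      best_area <- area
      ur <- range(u); vr <- range(v)
      uu <- ur[c(1, 2, 2, 1)]; vv <- vr[c(1, 1, 2, 2)]
      best <- cbind(x = ct * uu - st * vv, y = st * uu + ct * vv)
    }
  }
  list(area = best_area, corners = best)
}

# Independent space-volume integrator: scalar loop over unit squares with
# all four pixels in the ROI, each square split along the same diagonal,
# tetra volumes from the determinant form. Deliberately naive.
brute_space_volume <- function(depth, roi, intr) {
  h <- nrow(depth); w <- ncol(depth)
  p3 <- function(r, c) {
    d <- depth[r, c]
    c(d * ((c - 1) - intr$cx) / intr$f, d * ((r - 1) - intr$cy) / intr$f, d)
  }
  total <- 0
  for (r in seq_len(h - 1)) {
    for (c in seq_len(w - 1)) {
      if (roi[r, c] && roi[r, c + 1] && roi[r + 1, c] && roi[r + 1, c + 1]) {
        tl <- p3(r, c); tr <- p3(r, c + 1)
        bl <- p3(r + 1, c); br <- p3(r + 1, c + 1)
        total <- total + triple_volume(tl, tr, br) + triple_volume(tl, br, bl)
      }
    }
  }
  total / 1000
}

# Maximum distance between two corner sets, matching each corner of `a`
# to its nearest in `b` (order/starting-vertex independent).
corner_dist <- function(a, b) {
  max(apply(a, 1, function(p) {
    min(sqrt((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2))
  }))
}

# A filled disc mask.
disc_mask <- function(h, w, cy, cx, r) {
  xg <- matrix(rep(0:(w - 1), each = h), h, w)
  yg <- matrix(rep(0:(h - 1), times = w), h, w)
  (xg - cx)^2 + (yg - cy)^2 <= r^2
}
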