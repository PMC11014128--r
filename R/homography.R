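#' Estimate a homography from four point correspondences
#'
#' Solves for the eight unknown entries of the 3x3 projective matrix `H`
#' (bottom-right entry fixed at 1) that maps each source point `(x_k, y_k)`
#' onto its target `(xt_k, yt_k)`. The four correspondences are substituted
#' into the projective mapping to form the classical 8x8 linear system in
#' `h1..h8`, which is solved with a general linear solver (mathematically
#' identical to inverting the coefficient matrix, numerically more stable).
#'
#' @param src 4x2 matrix of source points (columns x, y), pixel coordinates.
#' @param dst 4x2 matrix of target points in the same order.
#' @return A 3x3 homography matrix with `[3, 3] == 1`, of class
#'   `"homography"`.
#' @details No three of the four source (or target) points may be collinear;
#'   a degenerate configuration makes the linear system singular and is
#'   reported as an error.
#' @examples
#' src <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' estimate_homography(src, src + cbind(rep(5, 4), rep(-3, 4)))
#' @export
estimate_homography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (!all(dim(src) == c(4L, 2L)) || !all(dim(dst) == c(4L, 2L)))
    stop("'src' and 'dst' must be 4x2 point matrices")
  a <- matrix(0, 8, 8)
  b <- numeric(8)
  for (k in 1:4) {
    x <- src[k, 1]; y <- src[k, 2]
    xt <- dst[k, 1]; yt <- dst[k, 2]
    a[2 * k - 1, ] <- c(x, y, 1, 0, 0, 0, -x * xt, -y * xt)
    a[2 * k, ]     <- c(0, 0, 0, x, y, 1, -x * yt, -y * yt)
    b[2 * k - 1] <- xt
    b[2 * k]     <- yt
  }
  h <- tryCatch(solve(a, b), error = function(e)
    stop("degenerate point configuration: homography system is singular",
         call. = FALSE))
  H <- rbind(c(h[1], h[2], h[3]),
             c(h[4], h[5], h[6]),
             c(h[7], h[8], 1))
  if (abs(det(H)) < .Machine$double.eps)
    stop("estimated homography is not invertible")
  structure(H, class = c("homography", "matrix"))
}

#' Apply a homography to 2D points
#'
#' @param H 3x3 homography matrix.
#' @param pts n x 2 matrix of points (columns x, y).
#' @return n x 2 matrix of mapped points.
#' @export
apply_homography <- function(H, pts) {
  pts <- rbind(pts)
  p <- unclass(H) %*% rbind(t(pts), 1)
  out <- cbind(x = p[1, ] / p[3, ], y = p[2, ] / p[3, ])
  rownames(out) <- NULL
  out
}

#' Warp an image with a homography
#'
#' Inverse-mapping warp into the target frame: each target pixel looks up
#' its pre-image under `H` in the source image. Depth images use
#' nearest-neighbor sampling, because interpolating across a depth
#' discontinuity would fabricate surfaces that exist in neither capture;
#' color (and label) images may use bilinear interpolation. Target pixels
#' whose pre-image falls outside the source are set to `fill`
#' (0 for depth, black for color).
#'
#' @param img A matrix (depth, label mask) or H x W x 3 array (color).
#' @param H Homography mapping source pixel coordinates to target pixel
#'   coordinates (as returned by [estimate_homography()]).
#' @param method `"nearest"` (default, required for depth and label images)
#'   or `"bilinear"` (color only).
#' @param fill Value for unmapped target pixels.
#' @return Warped image with the same dimensions as `img`.
#' @export
warp_image <- function(img, H, method = c("nearest", "bilinear"), fill = 0) {
  method <- match.arg(method)
  Hinv <- solve(unclass(H))
  d <- dim(img)
  h <- d[1]; w <- d[2]
  # target pixel grid, 0-based (x = column, y = row)
  xt <- rep(0:(w - 1L), each = h)
  yt <- rep(0:(h - 1L), times = w)
  den <- Hinv[3, 1] * xt + Hinv[3, 2] * yt + Hinv[3, 3]
  xs <- (Hinv[1, 1] * xt + Hinv[1, 2] * yt + Hinv[1, 3]) / den
  ys <- (Hinv[2, 1] * xt + Hinv[2, 2] * yt + Hinv[2, 3]) / den

  sample_plane <- function(plane) {
    if (method == "nearest") {
      ci <- round(xs) + 1L; ri <- round(ys) + 1L
      ok <- ci >= 1L & ci <= w & ri >= 1L & ri <= h
      out <- rep(fill, length(xs))
      out[ok] <- plane[cbind(ri[ok], ci[ok])]
    } else {
      x0 <- floor(xs); y0 <- floor(ys)
      fx <- xs - x0; fy <- ys - y0
      ok <- x0 >= 0 & x0 <= w - 2L & y0 >= 0 & y0 <= h - 2L
      out <- rep(fill, length(xs))
      r0 <- y0[ok] + 1L; c0 <- x0[ok] + 1L
      fxo <- fx[ok]; fyo <- fy[ok]
      out[ok] <-
        plane[cbind(r0,      c0)]      * (1 - fxo) * (1 - fyo) +
        plane[cbind(r0,      c0 + 1L)] * fxo       * (1 - fyo) +
        plane[cbind(r0 + 1L, c0)]      * (1 - fxo) * fyo +
        plane[cbind(r0 + 1L, c0 + 1L)] * fxo       * fyo
    }
    matrix(out, h, w)
  }

  if (length(d) == 2L) {
    sample_plane(img)
  } else {
    out <- array(fill, d)
    for (ch in seq_len(d[3])) out[, , ch] <- sample_plane(img[, , ch])
    out
  }
}

#' Find the four corners of the meal plate in a region mask
#'
#' Computes the minimum-area enclosing rectangle of the mask's convex hull
#' with the rotating-calipers sweep: the minimum-area rectangle has one side
#' collinear with a hull edge, so only hull-edge orientations need to be
#' examined. The rectangle's four vertices are returned ordered clockwise
#' (in image coordinates, y down) starting from the vertex nearest the
#' image origin.
#'
#' @param mask Logical or 0/1 matrix; nonzero pixels are the plate region.
#' @return 4x2 matrix of corner points (columns x, y) in pixel coordinates.
#' @export
find_plate_corners <- function(mask) {
  mask <- roi_as_logical(mask, dim(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3L) stop("degenerate region: fewer than 3 plate pixels")
  px <- idx[, 2] - 1  # x = column
  py <- idx[, 1] - 1  # y = row
  hull <- grDevices::chull(px, py)
  hx <- px[hull]; hy <- py[hull]
  if (length(hull) < 3L ||
      max(abs((hx - hx[1]) * (hy[2] - hy[1]) -
              (hy - hy[1]) * (hx[2] - hx[1]))) < 1e-9)
    stop("degenerate region: plate pixels are collinear")

  nh <- length(hull)
  edges <- cbind(hx[c(2:nh, 1)] - hx, hy[c(2:nh, 1)] - hy)
  angles <- unique(atan2(edges[, 2], edges[, 1]) %% (pi / 2))
  best <- NULL; best_area <- Inf
  for (th in angles) {
    ct <- cos(th); st <- sin(th)
    u <- ct * hx + st * hy
    v <- -st * hx + ct * hy
    area <- (max(u) - min(u)) * (max(v) - min(v))
    if (area < best_area) {
      best_area <- area
      best <- list(th = th, u = range(u), v = range(v))
    }
  }
  ct <- cos(best$th); st <- sin(best$th)
  uu <- best$u[c(1, 2, 2, 1)]
  vv <- best$v[c(1, 1, 2, 2)]
  corners <- cbind(x = ct * uu - st * vv, y = st * uu + ct * vv)
  order_corners(corners)
}

# Order four corners clockwise in image coordinates (y down), starting from
# the corner nearest the image origin (0, 0).
order_corners <- function(corners) {
  ctr <- colMeans(corners)
  # with y pointing down, increasing atan2 angle is clockwise on screen
  ord <- order(atan2(corners[, 2] - ctr[2], corners[, 1] - ctr[1]))
  corners <- corners[ord, , drop = FALSE]
  start <- which.min(corners[, 1]^2 + corners[, 2]^2)
  out <- corners[c(start:4, seq_len(start - 1L)), , drop = FALSE]
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

#' Register the post-meal capture onto the pre-meal capture
#'
#' Finds the plate's four corners in both plate masks, estimates the
#' homography that maps the post-meal corners onto the pre-meal corners
#' (corners are put in correspondence by their shared clockwise ordering,
#' which assumes the plate rotated by less than 45 degrees between the two
#' captures), and warps the post-meal color image, depth image, and food
#' masks with that single homography.
#'
#' @param pre_plate_mask,post_plate_mask Plate region masks for the two
#'   captures (logical or 0/1 matrices).
#' @param post_color Optional post-meal color image (H x W x 3, values in
#'   `[0, 1]`), warped with bilinear interpolation.
#' @param post_depth Optional post-meal depth image (mm), warped with
#'   nearest-neighbor sampling.
#' @param post_masks Optional label mask (or list of masks) warped with
#'   nearest-neighbor sampling.
#' @param pre_corners,post_corners Optional manual corner overrides (4x2
#'   matrices, clockwise from nearest the origin); when supplied the
#'   corresponding mask is not consulted.
#' @return A list with elements `H` (the fitted [estimate_homography()]
#'   matrix mapping post to pre pixel coordinates), `color`, `depth`,
#'   `masks` (warped counterparts of the inputs, `NULL` where absent), and
#'   `corners` (list of `pre` and `post` corner matrices).
#' @export
align_post_meal <- function(pre_plate_mask, post_plate_mask,
                            post_color = NULL, post_depth = NULL,
                            post_masks = NULL,
                            pre_corners = NULL, post_corners = NULL) {
  if (is.null(pre_corners)) pre_corners <- find_plate_corners(pre_plate_mask)
  if (is.null(post_corners)) post_corners <- find_plate_corners(post_plate_mask)
  H <- estimate_homography(src = post_corners, dst = pre_corners)
  warp1 <- function(m) warp_image(m, H, method = "nearest", fill = 0)
  masks <- if (is.null(post_masks)) NULL
           else if (is.list(post_masks)) lapply(post_masks, warp1)
           else warp1(post_masks)
  list(
    H = H,
    color = if (is.null(post_color)) NULL
            else warp_image(post_color, H, method = "bilinear", fill = 0),
    depth = if (is.null(post_depth)) NULL else warp1(post_depth),
    masks = masks,
    corners = list(pre = pre_corners, post = post_corners)
  )
}
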