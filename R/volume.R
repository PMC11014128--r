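#' Volume of a tetrahedron with its apex at the camera origin
#'
#' The space between the camera and the food surface is decomposed into
#' tetrahedra whose base triangles are back-projected pixel triples and
#' whose shared apex is the camera center. Each volume is computed as
#' `V = s * h / 3`, where `s` is the base triangle's area (half the norm of
#' the cross product of two base edge vectors) and `h` is the distance from
#' the origin to the base plane (from the plane's implicit coefficients).
#' A degenerate (collinear) base yields volume 0.
#'
#' @param v1,v2,v3 Base vertices: length-3 vectors `(X, Y, Z)` in mm, or
#'   n x 3 matrices for vectorized evaluation.
#' @return Volume(s) in mm^3 (nonnegative).
#' @examples
#' tetra_volume(c(1, 0, 1), c(0, 1, 1), c(0, 0, 1))  # 1/6
#' @export
tetra_volume <- function(v1, v2, v3) {
  v1 <- rbind(v1); v2 <- rbind(v2); v3 <- rbind(v3)
  e1 <- v2 - v1
  e2 <- v3 - v1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  s <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  # implicit plane through the base: p1*X + p2*Y + p3*Z = p4
  p1 <- v1[, 2] * (v2[, 3] - v3[, 3]) + v2[, 2] * (v3[, 3] - v1[, 3]) +
        v3[, 2] * (v1[, 3] - v2[, 3])
  p2 <- v1[, 3] * (v2[, 1] - v3[, 1]) + v2[, 3] * (v3[, 1] - v1[, 1]) +
        v3[, 3] * (v1[, 1] - v2[, 1])
  p3 <- v1[, 1] * (v2[, 2] - v3[, 2]) + v2[, 1] * (v3[, 2] - v1[, 2]) +
        v3[, 1] * (v1[, 2] - v2[, 2])
  p4 <- v1[, 1] * (v2[, 2] * v3[, 3] - v3[, 2] * v2[, 3]) +
        v2[, 1] * (v3[, 2] * v1[, 3] - v1[, 2] * v3[, 3]) +
        v3[, 1] * (v1[, 2] * v2[, 3] - v2[, 2] * v1[, 3])
  nrm <- sqrt(p1^2 + p2^2 + p3^2)
  h <- ifelse(nrm > 0, abs(p4) / nrm, 0)
  v <- s * h / 3
  v[s == 0] <- 0
  unname(v)
}

#' Triangulate the pixels of an ROI into unit triangles
#'
#' Every unit pixel square whose four corner pixels all belong to the ROI
#' is split along its top-left to bottom-right diagonal into two triangles
#' (one pixel wide and one pixel high). Squares touching pixels outside
#' the ROI are excluded: their depth values belong to other objects and
#' would fabricate wall surfaces. The same split direction is used for
#' every square, so the triangulation is deterministic.
#'
#' @param roi Logical or 0/1 matrix selecting the ROI.
#' @return Integer matrix with three columns holding the (column-major)
#'   linear pixel indices of each triangle's vertices; zero rows when fewer
#'   than one full square lies inside the ROI.
#' @export
triangulate_roi <- function(roi) {
  roi <- roi_as_logical(roi, dim(roi))
  h <- nrow(roi); w <- ncol(roi)
  if (h < 2L || w < 2L || !any(roi)) {
    return(matrix(integer(0), 0L, 3L,
                  dimnames = list(NULL, c("i1", "i2", "i3"))))
  }
  tl <- roi[-h, -w] & roi[-h, -1] & roi[-1, -w] & roi[-1, -1]
  sq <- which(tl)                      # squares with all 4 pixels in ROI
  if (!length(sq)) {
    return(matrix(integer(0), 0L, 3L,
                  dimnames = list(NULL, c("i1", "i2", "i3"))))
  }
  # top-left pixel (r, c) of each full square, in the (h-1) x (w-1) grid
  r <- (sq - 1L) %% (h - 1L) + 1L
  c <- (sq - 1L) %/% (h - 1L) + 1L
  i_tl <- (c - 1L) * h + r
  i_tr <- c * h + r
  i_bl <- i_tl + 1L
  i_br <- i_tr + 1L
  # diagonal from top-left to bottom-right
  tri <- rbind(cbind(i_tl, i_tr, i_br),
               cbind(i_tl, i_br, i_bl))
  dimnames(tri) <- list(NULL, c("i1", "i2", "i3"))
  tri
}

#' Space volume between the camera and a surface over an ROI
#'
#' Back-projects every ROI pixel of the depth image to a 3D point, splits
#' the ROI into unit pixel triangles, and sums the volumes of the
#' tetrahedra formed by each base triangle and the camera origin. The sum
#' is the volume of the 3D region between the camera and the imaged
#' surface over that ROI.
#'
#' @param depth Corrected depth image (mm, no zeros inside the ROI).
#' @param roi Logical or 0/1 matrix selecting the ROI; a label matrix can
#'   be combined with `id` to select one region.
#' @param intr A [camera_intrinsics()] object.
#' @param id Optional region id when `roi` is a label matrix.
#' @return A list of class `space_volume` with elements `volume_cm3`,
#'   `n_tetrahedra`, and `n_skipped_px` (ROI pixels not covered by any
#'   triangle, e.g. thin mask protrusions).
#' @examples
#' intr <- camera_intrinsics(100, 15.5, 11.5, 32, 24)
#' depth <- matrix(400, 24, 32)
#' roi <- matrix(TRUE, 24, 32)
#' space_volume(depth, roi, intr)  # (31*23) * 400^3 / (3 * 100^2) mm^3
#' @export
space_volume <- function(depth, roi, intr, id = NULL) {
  roi <- roi_as_logical(roi, dim(depth), id = id)
  pts <- backproject_roi(depth, roi, intr)   # errors on zeros inside ROI
  tri <- triangulate_roi(roi)
  if (nrow(tri) == 0L) {
    res <- list(volume_cm3 = 0, n_tetrahedra = 0L,
                n_skipped_px = sum(roi))
    class(res) <- "space_volume"
    return(res)
  }
  P <- cbind(as.vector(pts$X), as.vector(pts$Y), as.vector(pts$Z))
  vols <- tetra_volume(P[tri[, 1], , drop = FALSE],
                       P[tri[, 2], , drop = FALSE],
                       P[tri[, 3], , drop = FALSE])
  covered <- unique(as.vector(tri))
  res <- list(volume_cm3 = sum(vols) / 1000,
              n_tetrahedra = nrow(tri),
              n_skipped_px = sum(roi) - length(covered))
  class(res) <- "space_volume"
  res
}

#' @export
print.space_volume <- function(x, ...) {
  cat(sprintf("space volume: %.2f cm^3 (%d tetrahedra, %d ROI px skipped)\n",
              x$volume_cm3, x$n_tetrahedra, x$n_skipped_px))
  invisible(x)
}

#' Estimate per-food intake from a pre/post depth-image pair
#'
#' Eating lowers the food surface, moving it farther from a top-down
#' camera, so the camera-to-surface space volume grows. The intake of food
#' `i` is therefore `space_volume(post, roi_i) - space_volume(pre, roi_i)`,
#' with both volumes integrated over the *same* ROI taken from the
#' pre-meal segmentation. The post-meal depth image must already be
#' aligned ([align_post_meal()]) and compensated
#' ([compensate_warped_depth()]). The estimate is signed: a negative value
#' flags alignment or noise problems rather than being hidden by clamping.
#'
#' @param pre_depth Corrected pre-meal depth image (mm).
#' @param post_depth Aligned + compensated post-meal depth image (mm).
#' @param rois Label matrix from the pre-meal segmentation (0 background,
#'   region ids > 0), or a named list of logical ROI matrices.
#' @param intr A [camera_intrinsics()] object.
#' @return A data frame with one row per food: `region`, `name`,
#'   `pre_cm3`, `post_cm3`, `intake_cm3`.
#' @export
estimate_intake <- function(pre_depth, post_depth, rois, intr) {
  if (!identical(dim(pre_depth), dim(post_depth)))
    stop("pre and post depth images differ in dimensions")
  roi_list <- as_roi_list(rois, dim(pre_depth))
  rows <- lapply(seq_along(roi_list), function(i) {
    roi <- roi_list[[i]]
    pre <- space_volume(pre_depth, roi, intr)
    post <- space_volume(post_depth, roi, intr)
    data.frame(region = i, name = names(roi_list)[i],
               pre_cm3 = pre$volume_cm3, post_cm3 = post$volume_cm3,
               intake_cm3 = post$volume_cm3 - pre$volume_cm3)
  })
  out <- do.call(rbind, rows)
  neg <- out$name[out$intake_cm3 < 0]
  if (length(neg))
    warning("negative intake estimate for: ", paste(neg, collapse = ", "),
            " (possible alignment or noise problem)", call. = FALSE)
  out
}

#' Volume of a single object against the empty-table background
#'
#' Difference of the empty-table space volume and the object-scene space
#' volume over the object's ROI. Geometrically this is the volume of the
#' object's silhouette shadow frustum: the region between the imaged
#' object surface and the table along the camera rays. It equals the
#' object's true volume only insofar as the object is low or its sides
#' follow the viewing rays; for a tall vertical-walled object it also
#' includes the space the object obscures below its silhouette. A single
#' capture cannot separate the two - which is exactly why intake
#' estimation differences two aligned captures instead.
#'
#' @param depth Corrected depth image of the scene containing the object.
#' @param background Corrected depth image of the empty table.
#' @param roi Object ROI (logical/0-1 matrix, or label matrix with `id`).
#' @inheritParams space_volume
#' @return Object volume in cm^3.
#' @export
object_volume <- function(depth, background, roi, intr, id = NULL) {
  space_volume(background, roi, intr, id = id)$volume_cm3 -
    space_volume(depth, roi, intr, id = id)$volume_cm3
}

# Normalize an ROI specification (label matrix or list of masks) to a named
# list of logical matrices.
as_roi_list <- function(rois, dims) {
  if (is.list(rois)) {
    out <- lapply(rois, roi_as_logical, dims = dims)
    if (is.null(names(out))) names(out) <- paste0("region_", seq_along(out))
    return(out)
  }
  if (!is.matrix(rois)) stop("'rois' must be a label matrix or list of masks")
  if (!identical(dim(rois), as.integer(dims)))
    stop("ROI dimensions do not match the depth images")
  ids <- sort(setdiff(unique(as.vector(rois)), 0))
  labels <- attr(rois, "food_labels")
  out <- lapply(ids, function(k) rois == k)
  names(out) <- vapply(ids, function(k) {
    nm <- if (is.null(labels)) NA_character_ else labels[as.character(k)]
    if (is.na(nm)) paste0("region_", k) else unname(nm)
  }, character(1))
  out
}
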