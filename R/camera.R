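#' Camera intrinsics for the pinhole model
#'
#' Bundles the focal length and optical center of a pinhole camera with the
#' image dimensions. The focal length `f` is expressed in pixel units (the
#' distance from the camera center to the image plane measured in pixels);
#' `(cx, cy)` is the optical center, which need not be the image center.
#'
#' @param f Focal length in pixel units; must be positive.
#' @param cx,cy Optical center column and row, in 0-based pixel coordinates.
#' @param width,height Image dimensions in pixels.
#' @return An object of class `camera_intrinsics`.
#' @examples
#' camera_intrinsics(598.05, 319.48, 241.50, 640, 480)
#' @export
camera_intrinsics <- function(f, cx, cy, width, height) {
  stopifnot(is.numeric(f), length(f) == 1L, is.finite(f))
  if (f <= 0) stop("focal length 'f' must be positive")
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stop("image dimensions must be positive")
  if (cx < 0 || cx >= width) stop("'cx' must lie in [0, width)")
  if (cy < 0 || cy >= height) stop("'cy' must lie in [0, height)")
  structure(
    list(f = as.numeric(f), cx = as.numeric(cx), cy = as.numeric(cy),
         width = width, height = height),
    class = "camera_intrinsics"
  )
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: f = %.4g px, c = (%.4g, %.4g), %d x %d\n",
              x$f, x$cx, x$cy, x$width, x$height))
  invisible(x)
}

#' Read or write camera intrinsics as a YAML or JSON config
#'
#' The config must contain the keys `f`, `cx`, `cy`, `width`, `height`.
#' The format is chosen from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path Path to the config file.
#' @return `read_intrinsics()` returns a [camera_intrinsics()] object;
#'   `write_intrinsics()` returns `path` invisibly.
#' @export
read_intrinsics <- function(path) {
  if (!file.exists(path)) stop("intrinsics config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("f", "cx", "cy", "width", "height")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("intrinsics config missing keys: ",
                         paste(miss, collapse = ", "))
  camera_intrinsics(cfg$f, cfg$cx, cfg$cy, cfg$width, cfg$height)
}

#' @param intr A [camera_intrinsics()] object.
#' @rdname read_intrinsics
#' @export
write_intrinsics <- function(intr, path) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  lst <- unclass(intr)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' Back-project depth pixels to 3D camera coordinates
#'
#' Inverts the pinhole projection: a pixel `(x, y)` with measured depth `d`
#' (mm along the capture direction) maps to the 3D point
#' `(d * (x - cx) / f, d * (y - cy) / f, d)` with the camera at the origin
#' and Z along the capture direction.
#'
#' @param x,y Pixel coordinates (0-based, x = column, y = row); vectors of
#'   equal length are accepted.
#' @param depth Depth values in mm, same length as `x`; all must be > 0.
#' @param intr A [camera_intrinsics()] object.
#' @return A numeric matrix with columns `X`, `Y`, `Z` (mm), one row per
#'   input pixel.
#' @examples
#' intr <- camera_intrinsics(598.05, 319.48, 241.50, 640, 480)
#' backproject(319.48, 241.50, 400, intr)  # optical center -> on the Z axis
#' @export
backproject <- function(x, y, depth, intr) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  n <- length(x)
  if (length(y) != n || length(depth) != n)
    stop("'x', 'y' and 'depth' must have equal length")
  if (any(!is.finite(depth)) || any(depth <= 0))
    stop("invalid depth: all depth values must be positive and finite")
  cbind(X = depth * (x - intr$cx) / intr$f,
        Y = depth * (y - intr$cy) / intr$f,
        Z = depth)
}

#' Project 3D camera-frame points to pixel coordinates
#'
#' The forward pinhole projection `x = f*X/Z + cx`, `y = f*Y/Z + cy`;
#' the exact inverse of [backproject()] for points with `Z > 0`.
#'
#' @param pts Matrix with columns `X`, `Y`, `Z` (mm).
#' @inheritParams backproject
#' @return Matrix with columns `x`, `y` in pixel coordinates.
#' @export
project_points <- function(pts, intr) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  pts <- rbind(pts)
  if (any(pts[, 3] <= 0)) stop("cannot project points with Z <= 0")
  cbind(x = intr$f * pts[, 1] / pts[, 3] + intr$cx,
        y = intr$f * pts[, 2] / pts[, 3] + intr$cy)
}

#' Back-project every ROI pixel of a depth image
#'
#' Converts each pixel inside the region of interest into a 3D point,
#' keeping the pixel-grid arrangement so neighbor relations survive (the
#' tetrahedral integration relies on them). All ROI pixels must carry a
#' measured depth; run the depth corrections first.
#'
#' @param depth Depth image matrix (mm, 0 = unmeasured).
#' @param roi Logical or 0/1 matrix of the same dimensions selecting the ROI.
#' @inheritParams backproject
#' @return A list of three matrices `X`, `Y`, `Z` shaped like `depth`, with
#'   `NA` outside the ROI.
#' @export
backproject_roi <- function(depth, roi, intr) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  roi <- roi_as_logical(roi, dim(depth))
  bad <- which(roi & depth <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "unmeasured depth inside ROI at pixel (x = %d, y = %d)%s",
      bad[1, 2] - 1L, bad[1, 1] - 1L,
      if (nrow(bad) > 1L) sprintf(" and %d more", nrow(bad) - 1L) else ""))
  }
  h <- nrow(depth); w <- ncol(depth)
  xg <- matrix(rep(0:(w - 1L), each = h), h, w)   # x = column index
  yg <- matrix(rep(0:(h - 1L), times = w), h, w)  # y = row index
  Z <- ifelse(roi, depth, NA_real_)
  list(X = Z * (xg - intr$cx) / intr$f,
       Y = Z * (yg - intr$cy) / intr$f,
       Z = Z)
}

# Coerce an ROI argument (logical matrix, 0/1 matrix, or label matrix with a
# region id) to a logical matrix, checking dimensions.
roi_as_logical <- function(roi, dims, id = NULL) {
  if (!is.matrix(roi)) stop("ROI must be a matrix")
  if (!is.null(dims) && !identical(dim(roi), as.integer(dims)))
    stop(sprintf("ROI dimensions (%d x %d) do not match image (%d x %d)",
                 nrow(roi), ncol(roi), dims[1], dims[2]))
  if (is.logical(roi)) return(roi)
  if (is.null(id)) roi != 0 else roi == id
}
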