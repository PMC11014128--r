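#' Create a region mask with a food-label map
#'
#' A region mask is an integer label matrix: 0 is background and each id
#' `k > 0` marks the pixels of one region (one food, or the meal plate).
#' The id-to-name map travels with the matrix as the `"food_labels"`
#' attribute (a named character vector, names = ids).
#'
#' @param labels Integer matrix of region ids (0 = background).
#' @param label_map Named character vector or list mapping ids (as names)
#'   to food-name strings, e.g. `c("1" = "kimchi")`.
#' @return The label matrix with class `region_mask`.
#' @export
region_mask <- function(labels, label_map = NULL) {
  if (!is.matrix(labels)) stop("'labels' must be a matrix")
  if (any(labels < 0)) stop("region ids must be nonnegative")
  ids <- sort(setdiff(unique(as.vector(labels)), 0))
  if (length(ids) && !identical(as.integer(ids), seq_along(ids)))
    stop("region ids must be contiguous from 1")
  if (!is.null(label_map)) {
    label_map <- unlist(label_map)
    attr(labels, "food_labels") <- stats::setNames(as.character(label_map),
                                                   names(label_map))
  }
  class(labels) <- c("region_mask", class(matrix()))
  labels
}

#' Read or write per-food region masks
#'
#' Masks are stored as an 8-bit grayscale label PNG (pixel value = region
#' id) with a JSON sidecar mapping ids to food names, e.g.
#' `{"1": "kimchi"}`. The round trip is lossless for up to 255 regions.
#'
#' @param path Path to the label PNG; the sidecar is `<path>.json` (or
#'   supply `label_path`).
#' @param label_path Optional explicit path for the JSON label map.
#' @param intr Optional [camera_intrinsics()]; when given, the mask
#'   dimensions are checked against it.
#' @return `load_masks()` returns a [region_mask()]; `save_masks()`
#'   returns `path` invisibly.
#' @export
load_masks <- function(path, label_path = paste0(path, ".json"),
                       intr = NULL) {
  if (!file.exists(path)) stop("mask image not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  labels <- round(img * 255)
  if (!is.null(intr) &&
      !identical(dim(labels), c(intr$height, intr$width)))
    stop(sprintf("mask dimensions (%d x %d) do not match intrinsics (%d x %d)",
                 nrow(labels), ncol(labels), intr$height, intr$width))
  label_map <- NULL
  if (file.exists(label_path)) {
    lm <- jsonlite::read_json(label_path, simplifyVector = TRUE)
    label_map <- stats::setNames(as.character(lm), names(lm))
  }
  region_mask(labels, label_map)
}

#' @param mask A [region_mask()] (or plain label matrix).
#' @rdname load_masks
#' @export
save_masks <- function(mask, path, label_path = paste0(path, ".json")) {
  if (max(mask) > 255) stop("label PNGs support at most 255 regions")
  png::writePNG(unclass(mask) / 255, path)
  lm <- attr(mask, "food_labels")
  if (!is.null(lm))
    jsonlite::write_json(as.list(lm), label_path, auto_unbox = TRUE)
  invisible(path)
}

#' Intersection over union of two pixel regions
#'
#' `IoU = |G intersect D| / |G union D|`, the standard overlap measure
#' between a ground-truth region `G` and a detected region `D`. Two empty
#' regions agree vacuously and score 1.
#'
#' @param g,d Logical/0-1 matrices of identical dimensions (or label
#'   matrices combined with `g_id`/`d_id`).
#' @param g_id,d_id Optional region ids when `g`/`d` are label matrices.
#' @return IoU in `[0, 1]`.
#' @export
compute_iou <- function(g, d, g_id = NULL, d_id = NULL) {
  g <- roi_as_logical(g, dim(g), id = g_id)
  d <- roi_as_logical(d, dim(d), id = d_id)
  if (!identical(dim(g), dim(d))) stop("mask dimensions differ")
  uni <- sum(g | d)
  if (uni == 0) return(1)
  sum(g & d) / uni
}

#' Define per-food ROIs from the pre-meal segmentation
#'
#' The food regions detected in the *pre-meal* image are designated as the
#' regions of interest; the identical pixel set is then integrated in both
#' the pre- and post-meal depth images so that the obscured-space volumes
#' cancel in the difference.
#'
#' @param pre_masks Pre-meal [region_mask()] (label matrix).
#' @param exclude Region ids to leave out (e.g. the plate region id).
#' @return Named list of logical ROI matrices, one per food region.
#' @export
rois_from_premeal <- function(pre_masks, exclude = integer(0)) {
  if (!is.matrix(pre_masks)) stop("'pre_masks' must be a label matrix")
  keep <- sort(setdiff(setdiff(unique(as.vector(pre_masks)), 0), exclude))
  labels <- attr(pre_masks, "food_labels")
  out <- lapply(keep, function(k) unclass(pre_masks) == k)
  names(out) <- vapply(keep, function(k) {
    nm <- if (is.null(labels)) NA_character_ else labels[as.character(k)]
    if (is.na(nm)) paste0("region_", k) else unname(nm)
  }, character(1))
  out
}
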