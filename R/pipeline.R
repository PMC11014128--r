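#' Run the full intake-estimation pipeline
#'
#' End-to-end orchestration: capture correction (temporal mode + hole
#' filling) on the raw depth stacks, plate-corner alignment of the
#' post-meal capture, depth compensation against the empty-table
#' background, ROI definition from the pre-meal food regions, space-volume
#' integration, and per-food intake estimation. The run is deterministic
#' given its inputs.
#'
#' @param config A named list (or path to a YAML/JSON file) with entries:
#' \describe{
#'   \item{intrinsics}{[camera_intrinsics()] object, or path to a YAML/JSON
#'     intrinsics config.}
#'   \item{pre, post}{Each a list with `depth` (single 16-bit PNG path or
#'     depth matrix) or `depth_stack` (directory of frame PNGs or list of
#'     matrices), and `masks` (label PNG path or [region_mask()]); `post`
#'     may also carry `color` (PNG path or array).}
#'   \item{background}{`depth` or `depth_stack` of the empty table, same
#'     forms as above.}
#'   \item{plate_region_id}{Label id of the meal plate in both mask images
#'     (default 1); excluded from the food ROIs.}
#'   \item{exclude_region_ids}{Further label ids that are not foods (e.g.
#'     a bowl body) and get no intake estimate.}
#' }
#' @param out Optional path; when given the report is written there as
#'   JSON (see [write_intake_report()]).
#' @return An `intake_report` list: `foods` (data frame with per-food pre
#'   and post space volumes and intake in cm^3, plus flags), `homography`,
#'   `alignment_iou` (plate-mask IoU after warping), `clamped_px`,
#'   `config` (echo of file-backed inputs), `stages` (completed stage
#'   names). On failure the error is re-raised with the failing stage
#'   name; the partial report so far is attached to the condition as
#'   `partial_report`.
#' @export
run_pipeline <- function(config, out = NULL) {
  report <- list(schema = "intakevol-report/1", foods = NULL,
                 homography = NULL, alignment_iou = NA_real_,
                 clamped_px = 0L, stages = character(0))
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      cond <- simpleError(paste0("pipeline stage '", name, "': ",
                                 conditionMessage(e)))
      cond$partial_report <- report
      stop(cond)
    })
    report$stages <<- c(report$stages, name)
    res
  }

  cfg <- stage("config", {
    if (is.character(config)) {
      config <- if (grepl("\\.json$", config, ignore.case = TRUE))
        jsonlite::read_json(config, simplifyVector = TRUE)
      else yaml::read_yaml(config)
    }
    for (key in c("intrinsics", "pre", "post", "background")) {
      if (is.null(config[[key]])) stop("config entry '", key, "' is missing")
    }
    config
  })
  report$config <- config_echo(cfg)

  intr <- stage("intrinsics", {
    if (inherits(cfg$intrinsics, "camera_intrinsics")) cfg$intrinsics
    else read_intrinsics(cfg$intrinsics)
  })

  pre_depth <- stage("pre_capture", load_capture_depth(cfg$pre))
  post_depth <- stage("post_capture", load_capture_depth(cfg$post))
  background <- stage("background", load_capture_depth(cfg$background))

  pre_masks <- stage("pre_masks", load_capture_masks(cfg$pre, intr))
  post_masks <- stage("post_masks", load_capture_masks(cfg$post, intr))
  post_color <- stage("post_color", {
    cc <- cfg$post$color
    if (is.null(cc) || !is.character(cc)) cc else png::readPNG(cc)
  })

  plate_id <- if (is.null(cfg$plate_region_id)) 1L
              else as.integer(cfg$plate_region_id)

  aligned <- stage("alignment", {
    align_post_meal(
      pre_plate_mask = unclass(pre_masks) == plate_id,
      post_plate_mask = unclass(post_masks) == plate_id,
      post_color = post_color,
      post_depth = post_depth,
      post_masks = unclass(post_masks))
  })
  report$homography <- unclass(aligned$H)
  report$alignment_iou <- compute_iou(unclass(pre_masks) == plate_id,
                                      aligned$masks == plate_id)

  post_comp <- stage("compensation", {
    compensate_warped_depth(aligned$depth, background, aligned$H)
  })
  report$clamped_px <- attr(post_comp, "clamped")

  rois <- stage("roi_definition", {
    excl <- c(plate_id, as.integer(cfg$exclude_region_ids))
    rois_from_premeal(pre_masks, exclude = excl)
  })

  foods <- stage("intake_estimation", {
    est <- withCallingHandlers(
      estimate_intake(pre_depth, post_comp, rois, intr),
      warning = function(w) invokeRestart("muffleWarning"))
    est$negative <- est$intake_cm3 < 0
    est
  })
  report$foods <- foods
  report$aligned <- aligned
  report$post_depth_compensated <- post_comp
  report$pre_depth <- pre_depth
  class(report) <- "intake_report"
  if (!is.null(out)) write_intake_report(report, out)
  report
}

# Resolve a capture's depth input: single frame (path or matrix) or a stack
# (directory or list of matrices); stacks go through correct_capture(),
# single frames skip the temporal mode but still get hole filling.
load_capture_depth <- function(entry) {
  if (!is.null(entry$depth_stack)) {
    stack <- if (is.character(entry$depth_stack))
      read_depth_stack(entry$depth_stack)
    else entry$depth_stack
    correct_capture(stack)
  } else if (!is.null(entry$depth)) {
    d <- if (is.character(entry$depth)) read_depth_png(entry$depth)
         else entry$depth
    if (any(d == 0)) fill_unmeasured(d) else d
  } else {
    stop("capture needs a 'depth' image or a 'depth_stack'")
  }
}

load_capture_masks <- function(entry, intr) {
  m <- entry$masks
  if (is.null(m)) stop("capture entry has no 'masks'")
  if (is.character(m)) m <- load_masks(m, intr = intr)
  if (!identical(dim(m), c(intr$height, intr$width)))
    stop("mask dimensions do not match the camera intrinsics")
  m
}

config_echo <- function(cfg) {
  prune <- function(x) {
    if (is.list(x)) lapply(x, prune)
    else if (is.character(x) || is.numeric(x)) x
    else sprintf("<in-memory %s>", class(x)[1])
  }
  prune(cfg)
}

#' @export
print.intake_report <- function(x, ...) {
  cat("intake report (", x$schema, ")\n", sep = "")
  cat(sprintf("  plate alignment IoU: %.3f; clamped px: %d\n",
              x$alignment_iou, x$clamped_px))
  f <- x$foods
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-20s pre %8.2f cm^3  post %8.2f cm^3  intake %8.2f cm^3%s\n",
                f$name[i], f$pre_cm3[i], f$post_cm3[i], f$intake_cm3[i],
                if (f$negative[i]) "  [negative]" else ""))
  }
  invisible(x)
}

#' Write an intake report as JSON
#'
#' Per-food pre/post space volumes and intakes are reported in cm^3 with
#' two decimals; the homography, plate-alignment IoU, and clamped-pixel
#' count are included for auditability.
#'
#' @param report An `intake_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_intake_report <- function(report, path) {
  f <- report$foods
  out <- list(
    schema = report$schema,
    foods = lapply(seq_len(nrow(f)), function(i) list(
      name = f$name[i],
      pre_space_volume_cm3 = round(f$pre_cm3[i], 2),
      post_space_volume_cm3 = round(f$post_cm3[i], 2),
      intake_cm3 = round(f$intake_cm3[i], 2),
      negative_intake = f$negative[i])),
    homography = report$homography,
    alignment_iou = report$alignment_iou,
    clamped_px = report$clamped_px,
    config = report$config
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
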