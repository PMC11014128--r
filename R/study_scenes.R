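#' Canonical study scenes
#'
#' Two ready-made scenes mirroring the capture setup the package is
#' designed for (top-down camera 40 cm above the table, 640x480 depth
#' frames): a single water bowl centered on a dinner plate, and a meal
#' tray carrying a water bowl and one low-profile side dish. They are used
#' throughout the tests and the reproduction script, and are convenient
#' starting points for experiments.
#'
#' The tableware dimensions are realistic and fixed: an 11.3 cm inner
#' diameter soup bowl (inner cross-section 100 cm^2, so each cm of liquid
#' depth is 100 cm^3), 5 cm tall with a 4 mm wall and 5 mm base, and a
#' 10 x 10 cm food slab whose height sets its volume (9 mm = 90 cm^3).
#' Liquid levels land on integer millimeters, matching the sensor's mm
#' quantization.
#'
#' @param intr A [camera_intrinsics()]; defaults to the reference camera
#'   (`f = 598.05`, `c = (319.48, 241.50)`, 640x480).
#' @param fill_mm Liquid depth in the bowl (20 mm = 200 cm^3).
#' @param slab_h_mm Side-dish slab height (9 mm = 90 cm^3).
#' @return A [scene_spec()].
#' @export
scene_water_bowl <- function(intr = reference_intrinsics(), fill_mm = 20) {
  scene_spec(intr, table_depth_mm = 400,
             plate = plate_spec(c(0, 0), 240, 180, 10),
             solids = list(
               solid_bowl("water", c(0, 0), r_in_mm = sqrt(10000 / pi),
                          wall_mm = 4, height_mm = 50, base_mm = 5,
                          fill_mm = fill_mm)))
}

#' @rdname scene_water_bowl
#' @export
scene_meal_tray <- function(intr = reference_intrinsics(), fill_mm = 20,
                            slab_h_mm = 9) {
  scene_spec(intr, table_depth_mm = 400,
             plate = plate_spec(c(0, 0), 340, 240, 10),
             solids = list(
               solid_bowl("water", c(-70, 0), r_in_mm = sqrt(10000 / pi),
                          wall_mm = 4, height_mm = 50, base_mm = 5,
                          fill_mm = fill_mm),
               solid_cuboid("side_dish", c(80, 0), 100, 100, slab_h_mm)))
}

#' @rdname scene_water_bowl
#' @export
reference_intrinsics <- function() {
  camera_intrinsics(f = 598.05, cx = 319.48, cy = 241.50,
                    width = 640L, height = 480L)
}
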