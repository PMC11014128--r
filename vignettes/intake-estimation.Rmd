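---
title: "Estimating food intake from pre- and post-meal depth images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating food intake from pre- and post-meal depth images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

A fixed camera looks straight down at a meal plate and records a color and
a depth image before and after the meal. The depth image stores, per
pixel, the distance in millimeters from the camera to the first surface
along that pixel's ray (0 when the sensor could not measure). We want the
consumed volume of each food, without knowing the shape of any food or
container.

The central idea is differential: over the pixel region of one food (its
ROI), compute the volume of the 3D region between the camera and the
imaged surface — the *space volume* — in both captures, and report the
difference. A single capture of a food in a bowl cannot separate the food
from the space the bowl hides below the visible surface, but that hidden
space is *the same* in both captures once the two images are registered,
so it cancels in the difference. The package's `object_volume()`
documentation works through the single-capture case explicitly: there, the
measured quantity is the silhouette shadow frustum (object plus obscured
skirt), which is exactly why intake uses a registered difference instead.

## Pipeline and model

`run_pipeline()` executes, deterministically:

1. **Capture correction** (`correct_capture()`): per-pixel mode across the
   ~30-frame depth stack, then hole filling (below).
2. **Plate alignment** (`align_post_meal()`): plate corners in both
   captures by rotating calipers; a 4-point homography maps post-meal
   corners onto pre-meal corners; color/depth/masks are warped by it.
3. **Depth compensation** (`compensate_warped_depth()`): restores heights
   above the table using an empty-table background capture.
4. **ROI definition** (`rois_from_premeal()`): the pre-meal food regions,
   applied identically to both depth images.
5. **Volume integration** (`space_volume()`, `estimate_intake()`): unit
   pixel triangles, back-projected through the pinhole model, summed as
   camera-apex tetrahedra; intake = post − pre, in cm³.

The pinhole back-projection of pixel $(x, y)$ at depth $d$ is
$(X, Y, Z) = d \cdot \left( \tfrac{x - c_x}{f},\ \tfrac{y - c_y}{f},\ 1 \right)$,
with $f$ in pixel units. Each tetrahedron volume is $V = \tfrac13 s h$
with $s$ the base-triangle area (half cross-product norm) and $h$ the
origin-to-base-plane distance; this is algebraically the scalar triple
product $|v_1 \cdot (v_2 \times v_3)|/6$, and the test suite holds the two
routes to within $10^{-9}$ relative on random inputs. Over a constant
depth plane $Z$ an $a \times b$-pixel rectangular ROI integrates to
$(a-1)(b-1) \, Z^3 / (3 f^2)$, the closed form used as an independent
check.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `f`, `cx`, `cy` | 598.05, 319.48, 241.50 | px | reference camera, 640×480 |
| table distance | 400 | mm | top-down camera ≈ 40 cm above the table |
| frames per capture | 30 | — | enough for a reliable per-pixel mode |
| mean-fill window | 7×7 | px | matches the scale of edge dropout |
| jitter range | ±1 | mm | typical temporal flicker of consumer depth sensors |
| `p_stay` (jitter) | 0.7 | — | true value stays the most frequent one |
| dropout probability | 0.01 | per frame | unmeasured pixels appear near depth edges |
| dropout zone | 2 px of a >5 mm step | px | dropout clusters at discontinuities |

## Numerical choices

* **Pixel convention.** 0-based `(x = column, y = row)`, pixel centers at
  integer coordinates; no half-pixel offset anywhere, so the renderer, the
  corner finder, and the integrator agree.
* **Depth warping is nearest-neighbor.** Bilinear interpolation across a
  food/table edge would invent depths belonging to neither surface;
  nearest-neighbor moves measured values intact. Color warps bilinearly.
* **Compensation lookup.** The source pixel of a warped value is recovered
  by the same rounded inverse mapping the warp used, so value and
  correction refer to the same pixel; compensated depths below 0 are
  clamped and counted (`clamped` attribute, surfaced in the report).
* **Mode ties break toward the smaller value**, and zeros never vote:
  0 is a sentinel for "unmeasured", not data. A pixel is 0 after the mode
  only if it was 0 in every frame.
* **Hole filling averages measured neighbors only** — a plain 7×7 mean
  would drag values toward the zero sentinel — and iterates so holes wider
  than the window fill inward pass by pass; measured pixels are never
  touched.
* **Triangulation** splits every unit square whose four pixels are all in
  the ROI along the top-left→bottom-right diagonal. Squares touching
  non-ROI pixels are excluded: a boundary pixel's depth may belong to
  another object, and a tetrahedron built on it would fabricate a wall.
  Any consistent split differs only by boundary terms; fixing one makes
  runs bit-reproducible.
* **Corner correspondence.** Both corner sets are ordered clockwise
  starting from the corner nearest the image origin, which pairs them
  correctly whenever the plate rotates less than 45° between captures — a
  safe assumption within one meal, and manual corner overrides are
  accepted for anything wilder.
* **Intake is signed.** A negative estimate flags misalignment or noise;
  clamping would hide a real failure mode. The pipeline warns and marks
  the row instead.

## What the synthetic generator does and does not emulate

`render_scene()` ray-casts parametric solids (cuboids, cylinders, bowls
with a liquid fill) standing on a plate on a flat table, through the real
pinhole geometry: solids occupy their true 3D footprints, perspective
shrink and side-wall visibility behave as for a real camera, and depth is
quantized to integer millimeters like a real sensor. Ground-truth volumes
come from closed forms, never from the rendering. `make_meal_pair()`
derives the post-meal scene by removing requested volumes (heights or
liquid levels drop) and rigidly moving the plate with its solids, so the
true intake is known exactly. `apply_noise()` adds seeded temporal jitter
and edge dropout.

The chosen tableware is fixed and realistic: an 11.3 cm inner-diameter
soup bowl whose inner cross-section is 100 cm² (each mm of level is
10 cm³, so standard fills land on integer millimeters) and a 10 × 10 cm
low-profile slab standing in for a plated side dish. The scene scale —
640×480 frames, table at 400 mm — matches the reference capture setup,
and the test suite runs the full pipeline at that size.

What this does *not* cover, and hence what green tests do not prove about
real data: real foods have irregular, sloping, sometimes specular
surfaces and gaps between pieces; real segmentation masks are imperfect
(here they are rendered, i.e. pixel-accurate); real sensor noise is
spatially correlated and depth-dependent rather than i.i.d. ±1 mm; and
real plates are not perfect rectangles. A perfectly flat solid is also the
worst case for millimeter quantization: a surface landing on a half
millimeter rounds wholesale (0.5 mm × area), where an irregular real
surface would dither the rounding away.

Two residual error sources are inherent to the method and visible in the
synthetic results: *parallax* — the homography registers the plate plane,
so surfaces above that plane shift slightly more than the warp corrects,
which is why the registered-difference error grows with container height
and plate displacement — and *quantization* at ROI boundaries. The
reproduction script (`scripts/acceptance.R`) quantifies both scenarios
end-to-end.

## Known limitations

* One fixed camera; no extrinsics, no lens distortion model, single focal
  length (no separate fx/fy).
* The plate must be (approximately) rectangular and mostly visible;
  heavily occluded plates break the corner finder.
* Foods must stay within their pre-meal regions; food added after the
  first capture, or moved to another spot on the plate, violates the ROI
  assumption.
* Transparent or strongly reflective containers defeat depth sensing
  itself; nothing downstream can recover that.
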