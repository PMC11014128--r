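Package: intakevol
Title: Food Intake Estimation from Pre- and Post-Meal RGB-D Captures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates per-food intake amounts from pairs of color and depth
    images captured before and after a meal with a fixed top-down RGB-D
    camera. The post-meal capture is registered to the pre-meal capture by a
    four-corner plate homography (corners found by rotating calipers on the
    plate mask), warped depth values are compensated against an empty-table
    background so that heights above the table are preserved, and the intake
    of each food is obtained as the difference of camera-to-surface space
    volumes computed by tetrahedral integration over the food's region of
    interest. Includes depth denoising (temporal mode over frame stacks,
    7x7 valid-neighbor mean hole filling), 16-bit PNG depth image I/O, a
    perspective ray-casting synthetic scene generator with analytic
    ground-truth volumes, and an end-to-end pipeline with a machine-readable
    report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    yaml,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: zlib
Config/testthat/edition: 3
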