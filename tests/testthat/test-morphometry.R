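rect_segmentation <- function() {
  sil <- matrix(FALSE, 1000, 600)
  sil[201:800, 201:400] <- TRUE  # 200 px wide x 600 px tall
  segment_tree(sil, list(crown_trunk_row = 201, trunk_root_row = 1001,
                         flags = character(0)))
}

test_that("rectangle metrics match the pixel-count oracle", {
  cal <- calibration(300 / 2.54)
  met <- measure(rect_segmentation(), cal)
  expect_equal(met$trunk_area_cm2, 120000 / (300 / 2.54)^2,
               tolerance = 1e-12)
  expect_equal(met$trunk_height_cm, 600 / (300 / 2.54), tolerance = 1e-12)
  expect_equal(met$trunk_width_cm, 200 / (300 / 2.54), tolerance = 1e-12)
  r <- metrics_as_row(met)
  expect_equal(r$trunk_area_cm2, 8.60)
  expect_equal(r$trunk_height_cm, 5.08)
  expect_equal(r$trunk_width_cm, 1.69)
  # empty crown and root measure zero
  expect_equal(met$crown_area_cm2, 0)
  expect_equal(met$root_height_cm, 0)
})

test_that("rasterized disc area approaches pi r^2", {
  ppcm <- 300 / 2.54
  r_px <- 354
  m <- matrix(FALSE, 800, 800)
  rr <- row(m); cc <- col(m)
  m <- (rr - 400)^2 + (cc - 400)^2 <= r_px^2
  seg <- segment_tree(m, list(crown_trunk_row = 800 + 1,
                              trunk_root_row = 801, flags = character(0)))
  met <- measure(seg, calibration(ppcm))
  expect_lt(abs(met$crown_area_cm2 - pi * 3^2) / (pi * 3^2), 0.02)
})

test_that("metrics scale linearly in the calibration factor", {
  seg <- rect_segmentation()
  m1 <- measure(seg, calibration(100))
  m2 <- measure(seg, calibration(200))
  expect_equal(m2$trunk_area_cm2 * 4, m1$trunk_area_cm2, tolerance = 1e-12)
  expect_equal(m2$trunk_height_cm * 2, m1$trunk_height_cm,
               tolerance = 1e-12)
  expect_equal(m2$total_width_cm * 2, m1$total_width_cm, tolerance = 1e-12)
})

test_that("additive identities hold on every measured output", {
  for (seed in 16:18) {
    out <- render_tree(quick_spec(seed = seed, dpi = 100,
                                  root = if (seed %% 2)
                                    list(flare = 2.4, length_cm = 1)
                                  else NULL))
    sil <- out$segmentation$silhouette_mask
    seg <- segment_tree(sil, find_boundaries(width_profile(sil)))
    met <- measure(seg, calibration(100 / 2.54))
    expect_equal(met$total_area_cm2,
                 met$crown_area_cm2 + met$trunk_area_cm2 +
                   met$root_area_cm2, tolerance = 1e-12)
    expect_equal(met$total_height_cm,
                 met$crown_height_cm + met$trunk_height_cm +
                   met$root_height_cm, tolerance = 1e-12)
    expect_equal(met$total_width_cm,
                 max(met$crown_width_cm, met$trunk_width_cm,
                     met$root_width_cm), tolerance = 1e-12)
    expect_lte(met$crown_width_cm, met$total_width_cm)
  }
})

test_that("measure_file recovers renderer ground truth within 5%", {
  rt <- render_to_png(quick_spec(seed = 19, dpi = 150, noise_sigma = 8,
                                 annotation = TRUE))
  res <- measure_file(rt$path)
  truth <- rt$out$metrics
  for (v in c("crown_area_cm2", "trunk_area_cm2", "total_area_cm2"))
    expect_lt(abs(res$metrics[[v]] - truth[[v]]) / truth[[v]], 0.05)
})

test_that("measure_file names the failing stage", {
  blank <- tempfile(fileext = ".png")
  png::writePNG(matrix(1, 200, 150), blank)
  err <- tryCatch(measure_file(blank), error = identity)
  expect_match(conditionMessage(err), "binarize")
  expect_s3_class(err, "treedraw_no_ink_error")

  # page with only marginal text: cleaned away -> no drawing found
  margin_only <- tempfile(fileext = ".png")
  m <- matrix(1, 500, 400)
  m[485:490, 50:120] <- 0
  png::writePNG(m, margin_only)
  err2 <- tryCatch(measure_file(margin_only), error = identity)
  expect_match(conditionMessage(err2), "clean_mask")
  expect_s3_class(err2, "treedraw_no_drawing_error")
})

test_that("renderer recovery: median relative area error under 5%", {
  errs <- vapply(1:8, function(seed) {
    spec <- quick_spec(seed = 100 + seed, dpi = 100,
                       crown_semi_axes_cm = c(2.5 + 0.2 * seed,
                                              2 + 0.15 * seed),
                       noise_sigma = 6)
    rt <- render_to_png(spec)
    res <- measure_file(rt$path)
    truth <- rt$out$metrics
    abs(res$metrics$total_area_cm2 - truth$total_area_cm2) /
      truth$total_area_cm2
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("overlay and audit artifacts are written", {
  rt <- render_to_png(quick_spec(seed = 20, dpi = 100))
  ov <- tempfile(fileext = ".png")
  au <- tempfile(fileext = ".json")
  row <- cmd_measure(rt$path, overlay_path = ov, audit_path = au)
  expect_true(file.exists(ov))
  audit <- jsonlite::read_json(au)
  expect_true(all(c("otsu_threshold", "crown_trunk_row",
                    "pixels_per_cm") %in% names(audit)))
  expect_equal(nrow(row), 1)
})
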