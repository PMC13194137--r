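disc_mask <- function(nr, nc, cy, cx, r) {
  rr <- row(matrix(0, nr, nc)); cc <- col(matrix(0, nr, nc))
  (rr - cy)^2 + (cc - cx)^2 <= r^2
}

test_that("fill_silhouette leaves solids alone and fills outlines", {
  solid <- disc_mask(120, 120, 60, 60, 40)
  comp <- treedraw:::component_mask(solid)
  filled <- fill_silhouette(comp, closing_radius_px = 0)
  expect_identical(filled, solid)

  # 2-px circle outline -> solid disc of the outer radius
  outline <- disc_mask(120, 120, 60, 60, 40) & !disc_mask(120, 120, 60, 60, 38)
  filled <- fill_silhouette(treedraw:::component_mask(outline),
                            closing_radius_px = 2)
  target <- sum(disc_mask(120, 120, 60, 60, 40))
  expect_lt(abs(sum(filled) - target) / target, 0.06)

  # outline-style rendered tree recovers the filled ground truth within 5%
  out <- render_tree(quick_spec(seed = 8, dpi = 100, style = "outline",
                                stroke_px = 2, crown_jitter = 0))
  ink <- binarize(out$image)
  comp <- largest_component(clean_mask(ink, min_speck_px = 5))
  filled <- fill_silhouette(comp)
  truth <- sum(out$segmentation$silhouette_mask)
  expect_lt(abs(sum(filled) - truth) / truth, 0.05)
})

test_that("width profile matches rectangle and disc geometry", {
  rect <- matrix(FALSE, 100, 80)
  rect[20:79, 15:54] <- TRUE
  prof <- width_profile(rect)
  expect_true(all(prof$extent == 40))
  expect_equal(length(prof$extent), 60)
  expect_true(all(prof$count <= prof$extent))

  d <- disc_mask(200, 200, 100, 100, 70)
  prof <- width_profile(d)
  center <- which(prof$rows == 100)
  expect_lt(abs(prof$extent[center] - 140), 2)
  expect_error(width_profile(matrix(FALSE, 5, 5)),
               class = "treedraw_no_drawing_error")
})

test_that("boundary finder nails the lollipop junction and root flare", {
  # disc radius 100 px atop a 30-px-wide rectangle (at 300 dpi scale)
  ppcm <- 300 / 2.54
  spec <- synthetic_tree_spec(
    crown_semi_axes_cm = c(100 / ppcm, 100 / ppcm), crown_jitter = 0,
    trunk_top_cm = 30 / ppcm, trunk_bottom_cm = 30 / ppcm,
    trunk_height_cm = 600 / ppcm, dpi = 300, seed = 1)
  out <- render_tree(spec)
  prof <- width_profile(out$segmentation$silhouette_mask)
  b <- find_boundaries(prof, alpha = 0.5, run_rows = 5)
  expect_lte(abs(b$crown_trunk_row - out$segmentation$crown_trunk_row), 6)

  # root flare 2.5 x trunk width, beta = 1.6
  out2 <- render_tree(quick_spec(seed = 9, dpi = 150, crown_jitter = 0,
                                 root = list(flare = 2.5, length_cm = 1.2)))
  prof2 <- width_profile(out2$segmentation$silhouette_mask)
  b2 <- find_boundaries(prof2, beta = 1.6)
  expect_lte(abs(b2$trunk_root_row - out2$segmentation$trunk_root_row), 6)
})

test_that("degenerate monotone profiles fall back with a low-confidence flag", {
  rect <- matrix(FALSE, 100, 80)
  rect[20:79, 15:54] <- TRUE
  prof <- width_profile(rect)
  b <- find_boundaries(prof)
  expect_true("low-confidence-boundary" %in% b$flags)
  expect_equal(b$crown_trunk_row, 20)  # top row: no crown
  seg <- segment_tree(rect, b)
  expect_equal(sum(seg$crown_mask), 0)
})

test_that("segmentation is an exact partition of the silhouette", {
  for (seed in c(10, 11)) {
    out <- render_tree(quick_spec(seed = seed, dpi = 100,
                                  root = list(flare = 2.2, length_cm = 1)))
    sil <- out$segmentation$silhouette_mask
    prof <- width_profile(sil)
    seg <- segment_tree(sil, find_boundaries(prof))
    expect_equal(sum(seg$crown_mask) + sum(seg$trunk_mask) +
                   sum(seg$root_mask), sum(sil))
    expect_false(any(seg$crown_mask & seg$trunk_mask))
    expect_false(any(seg$trunk_mask & seg$root_mask))
    expect_false(any(seg$crown_mask & seg$root_mask))
    expect_true(all(which(rowSums(seg$crown_mask) > 0) <
                      seg$crown_trunk_row))
    if (sum(seg$root_mask) > 0)
      expect_true(all(which(rowSums(seg$root_mask) > 0) >=
                        seg$trunk_root_row))
  }
  # no-roots sentinel leaves the root mask empty
  out <- render_tree(quick_spec(seed = 12, dpi = 100))
  sil <- out$segmentation$silhouette_mask
  seg <- segment_tree(sil, find_boundaries(width_profile(sil)))
  expect_equal(sum(seg$root_mask), 0)
})

test_that("segmentation is equivariant under horizontal mirroring", {
  out <- render_tree(quick_spec(seed = 13, dpi = 100,
                                root = list(flare = 2.3, length_cm = 1)))
  sil <- out$segmentation$silhouette_mask
  mir <- sil[, rev(seq_len(ncol(sil)))]
  seg <- segment_tree(sil, find_boundaries(width_profile(sil)))
  seg_m <- segment_tree(mir, find_boundaries(width_profile(mir)))
  expect_equal(seg_m$crown_trunk_row, seg$crown_trunk_row)
  expect_equal(seg_m$trunk_root_row, seg$trunk_root_row)
  expect_identical(seg_m$crown_mask,
                   seg$crown_mask[, rev(seq_len(ncol(sil)))])
  expect_identical(seg_m$root_mask,
                   seg$root_mask[, rev(seq_len(ncol(sil)))])
})

test_that("segmentation is invariant under page translation", {
  out <- render_tree(quick_spec(seed = 14, dpi = 100))
  sil <- out$segmentation$silhouette_mask
  pad <- 37
  padded <- matrix(FALSE, nrow(sil) + 2 * pad, ncol(sil) + 2 * pad)
  padded[pad + seq_len(nrow(sil)), pad + seq_len(ncol(sil))] <- sil
  seg <- segment_tree(sil, find_boundaries(width_profile(sil)))
  seg_p <- segment_tree(padded, find_boundaries(width_profile(padded)))
  expect_equal(seg_p$crown_trunk_row, seg$crown_trunk_row + pad)
  expect_equal(sum(seg_p$crown_mask), sum(seg$crown_mask))
  expect_equal(sum(seg_p$trunk_mask), sum(seg$trunk_mask))
})

test_that("measured crown grows monotonically with drawn crown radius", {
  counts <- vapply(c(2.0, 2.6, 3.2, 3.8), function(a) {
    out <- render_tree(quick_spec(seed = 15, dpi = 100,
                                  crown_semi_axes_cm = c(a, 0.8 * a)))
    sil <- out$segmentation$silhouette_mask
    seg <- segment_tree(sil, find_boundaries(width_profile(sil)))
    sum(seg$crown_mask)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("measurements agree across 150 vs 300 dpi rendering", {
  res <- lapply(c(150, 300), function(dpi) {
    rt <- render_to_png(quick_spec(seed = 5, dpi = dpi, crown_jitter = 0.04,
                                   root = list(flare = 2.5,
                                               length_cm = 1.2)))
    measure_file(rt$path)
  })
  expect_lte(abs(res[[2]]$segmentation$crown_trunk_row / 2 -
                   res[[1]]$segmentation$crown_trunk_row), 2)
  expect_lte(abs(res[[2]]$segmentation$trunk_root_row / 2 -
                   res[[1]]$segmentation$trunk_root_row), 2)
  for (v in c("crown_area_cm2", "trunk_area_cm2", "total_area_cm2"))
    expect_lt(abs(res[[2]]$metrics[[v]] / res[[1]]$metrics[[v]] - 1), 0.03)
})
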