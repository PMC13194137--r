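# Calibrated metrics from a segmentation, and the single-image pipeline.

#' Construct a tree-metrics record
#'
#' Areas in cm^2, heights and widths in cm, for the crown, trunk and root
#' components plus derived totals. Totals are derived, never re-measured:
#' `total_area = crown + trunk + root` (exact, because the masks partition
#' the silhouette), `total_height` is the sum of the three contiguous row
#' extents, and `total_width` is the maximum of the component widths.
#'
#' @param crown_area_cm2,trunk_area_cm2,root_area_cm2 component areas.
#' @param crown_height_cm,trunk_height_cm,root_height_cm component heights.
#' @param crown_width_cm,trunk_width_cm,root_width_cm component widths.
#' @param confidence_flags character vector of quality flags.
#' @return an object of class `tree_metrics`.
#' @export
tree_metrics <- function(crown_area_cm2 = 0, trunk_area_cm2 = 0,
                         root_area_cm2 = 0,
                         crown_height_cm = 0, trunk_height_cm = 0,
                         root_height_cm = 0,
                         crown_width_cm = 0, trunk_width_cm = 0,
                         root_width_cm = 0,
                         confidence_flags = character(0)) {
  vals <- c(crown_area_cm2, trunk_area_cm2, root_area_cm2,
            crown_height_cm, trunk_height_cm, root_height_cm,
            crown_width_cm, trunk_width_cm, root_width_cm)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_treedraw("metrics must be finite and non-negative",
                  "treedraw_format_error")
  structure(list(
    crown_area_cm2 = crown_area_cm2, trunk_area_cm2 = trunk_area_cm2,
    root_area_cm2 = root_area_cm2,
    total_area_cm2 = crown_area_cm2 + trunk_area_cm2 + root_area_cm2,
    crown_height_cm = crown_height_cm, trunk_height_cm = trunk_height_cm,
    root_height_cm = root_height_cm,
    total_height_cm = crown_height_cm + trunk_height_cm + root_height_cm,
    crown_width_cm = crown_width_cm, trunk_width_cm = trunk_width_cm,
    root_width_cm = root_width_cm,
    total_width_cm = max(crown_width_cm, trunk_width_cm, root_width_cm),
    confidence_flags = confidence_flags), class = "tree_metrics")
}

# Row extent (px) and max per-row horizontal extent (px) of one mask.
.mask_extents <- function(mask) {
  if (!any(mask)) return(c(height = 0, width = 0))
  rows <- which(rowSums(mask) > 0)
  width <- max(apply(mask[rows, , drop = FALSE], 1, function(v) {
    w <- which(v)
    w[length(w)] - w[1] + 1L
  }))
  c(height = rows[length(rows)] - rows[1] + 1L, width = width)
}

#' Measure a segmented tree
#'
#' Converts pixel quantities into physical units: area = pixel count /
#' `pixels_per_cm`^2, height = row extent / `pixels_per_cm`, width = maximum
#' per-row horizontal extent / `pixels_per_cm`. Empty components measure 0.
#' Values are kept at full precision; use [format()] or
#' [metrics_as_row()] with `digits = 2` for reporting.
#'
#' @param segmentation a `tree_segmentation`.
#' @param cal a [calibration()].
#' @return a [tree_metrics()].
#' @export
measure <- function(segmentation, cal) {
  stopifnot(inherits(segmentation, "tree_segmentation"))
  if (!inherits(cal, "calibration") || cal$pixels_per_cm <= 0)
    stop_treedraw("invalid calibration", "treedraw_calibration_error")
  ppcm <- cal$pixels_per_cm
  comp <- list(crown = segmentation$crown_mask,
               trunk = segmentation$trunk_mask,
               root = segmentation$root_mask)
  area <- vapply(comp, sum, numeric(1)) / ppcm^2
  ext <- vapply(comp, .mask_extents, numeric(2))
  tree_metrics(
    crown_area_cm2 = area[["crown"]], trunk_area_cm2 = area[["trunk"]],
    root_area_cm2 = area[["root"]],
    crown_height_cm = ext["height", "crown"] / ppcm,
    trunk_height_cm = ext["height", "trunk"] / ppcm,
    root_height_cm = ext["height", "root"] / ppcm,
    crown_width_cm = ext["width", "crown"] / ppcm,
    trunk_width_cm = ext["width", "trunk"] / ppcm,
    root_width_cm = ext["width", "root"] / ppcm,
    confidence_flags = segmentation$flags)
}

#' Metrics as a one-row data frame
#'
#' @param metrics a [tree_metrics()].
#' @param digits decimal places (half-up rounding) for the interface scale;
#'   `NULL` keeps full precision.
#' @return one-row `data.frame` with the eleven metric columns and a
#'   `flags` column.
#' @export
metrics_as_row <- function(metrics, digits = 2) {
  stopifnot(inherits(metrics, "tree_metrics"))
  num <- metrics[!names(metrics) %in% "confidence_flags"]
  num <- lapply(num, function(v)
    if (is.null(digits)) v else round_half_up(v, digits))
  df <- as.data.frame(num)
  df$flags <- paste(metrics$confidence_flags, collapse = ";")
  df
}

#' @export
print.tree_metrics <- function(x, ...) {
  r <- metrics_as_row(x, digits = 2)
  cat("<tree_metrics> (cm / cm²)\n")
  cat(sprintf("  area : crown %.2f  trunk %.2f  root %.2f  total %.2f\n",
              r$crown_area_cm2, r$trunk_area_cm2, r$root_area_cm2,
              r$total_area_cm2))
  cat(sprintf("  height: crown %.2f  trunk %.2f  root %.2f  total %.2f\n",
              r$crown_height_cm, r$trunk_height_cm, r$root_height_cm,
              r$total_height_cm))
  cat(sprintf("  width : crown %.2f  trunk %.2f  total %.2f\n",
              r$crown_width_cm, r$trunk_width_cm, r$total_width_cm))
  if (nzchar(r$flags)) cat("  flags:", r$flags, "\n")
  invisible(x)
}

#' Measure a drawing file end-to-end
#'
#' Runs the full single-image pipeline: load, calibrate, binarize, clean,
#' select the largest component, fill the silhouette, locate boundaries,
#' segment, and measure. Any stage failure is re-signalled with the stage
#' name attached to the message.
#'
#' @param path image file (PNG/TIFF/JPEG).
#' @param config a [run_config()]; defaults used when omitted.
#' @return list with `metrics` ([tree_metrics()]), `segmentation`
#'   (`tree_segmentation`), `calibration`, and an `audit` record of stage
#'   parameters for provenance output.
#' @export
measure_file <- function(path, config = run_config()) {
  config <- as_run_config(config)
  image <- with_stage("load_image", load_image(path))
  cal <- with_stage("derive_calibration", {
    if (!is.null(config$pixels_per_cm))
      calibration(config$pixels_per_cm, source = "manual")
    else derive_calibration(image, page_width_cm = config$page_width_cm,
                            strict = config$strict_calibration)
  })
  speck <- config$min_speck_px * (cal$pixels_per_cm / (300 / 2.54))^2
  ink <- with_stage("binarize", binarize(image))
  cleaned <- with_stage("clean_mask",
    clean_mask(ink, min_speck_px = max(1, round(speck)),
               margin_frac = config$margin_frac,
               closing_radius_px = config$closing_radius_px))
  comp <- with_stage("largest_component", largest_component(cleaned))
  sil <- with_stage("fill_silhouette",
    fill_silhouette(comp, closing_radius_px = config$closing_radius_px))
  prof <- with_stage("width_profile",
    width_profile(sil, smooth_window_rows = config$smooth_window_rows))
  bnd <- with_stage("find_boundaries",
    find_boundaries(prof, alpha = config$alpha, beta = config$beta,
                    run_rows = config$run_rows))
  seg <- with_stage("segment_tree", segment_tree(sil, bnd))
  met <- with_stage("measure", measure(seg, cal))
  audit <- list(
    source = path,
    pixels_per_cm = cal$pixels_per_cm,
    calibration_source = cal$source,
    otsu_threshold = ink$threshold,
    min_speck_px = max(1, round(speck)),
    margin_frac = config$margin_frac,
    closing_radius_px = config$closing_radius_px,
    alpha = config$alpha, beta = config$beta,
    smooth_window = prof$window,
    crown_trunk_row = seg$crown_trunk_row,
    trunk_root_row = seg$trunk_root_row,
    flags = seg$flags)
  list(metrics = met, segmentation = seg, calibration = cal, audit = audit)
}

#' Write a review overlay image
#'
#' Renders the page with crown, trunk and root regions tinted (red, brown,
#' gray) over the scan for human review of the segmentation.
#'
#' @param image the source [raster_image()].
#' @param segmentation a `tree_segmentation`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(image, segmentation, path) {
  stopifnot(inherits(image, "raster_image"),
            inherits(segmentation, "tree_segmentation"))
  base <- pmin(pmax(image$pixels / 255, 0), 1)
  rgb <- array(rep(base, 3), dim = c(dim(base), 3))
  tint <- function(rgb, mask, col) {
    for (k in 1:3) {
      ch <- rgb[, , k]
      ch[mask] <- 0.5 * ch[mask] + 0.5 * col[k]
      rgb[, , k] <- ch
    }
    rgb
  }
  rgb <- tint(rgb, segmentation$crown_mask, c(0.9, 0.2, 0.2))
  rgb <- tint(rgb, segmentation$trunk_mask, c(0.6, 0.4, 0.1))
  rgb <- tint(rgb, segmentation$root_mask, c(0.4, 0.4, 0.4))
  png::writePNG(rgb, path)
  invisible(path)
}
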