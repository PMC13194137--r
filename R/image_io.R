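# Image loading and pixel-to-centimetre calibration.

#' Construct a raster image object
#'
#' A `raster_image` holds a scanned page as a rows x cols grayscale intensity
#' matrix with values in \[0, 255\] (0 = black ink, 255 = white paper), row 1
#' at the top of the page, plus optional physical-resolution metadata.
#'
#' @param pixels numeric matrix of intensities in \[0, 255\].
#' @param dpi scan resolution in dots per inch, or `NULL` when unknown.
#' @param source_path provenance string (file the image came from).
#' @return an object of class `raster_image`.
#' @export
raster_image <- function(pixels, dpi = NULL, source_path = "") {
  if (!is.matrix(pixels) || nrow(pixels) < 1 || ncol(pixels) < 1)
    stop_treedraw("pixels must be a non-empty matrix", "treedraw_format_error")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_treedraw("intensities must lie in [0, 255]", "treedraw_format_error")
  if (!is.null(dpi)) {
    if (!is_scalar_number(dpi) || dpi <= 0)
      stop_treedraw("dpi must be a positive finite number",
                    "treedraw_format_error")
  }
  structure(list(pixels = pixels, dpi = dpi, source_path = source_path),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px, dpi = %s, source = %s\n",
              nrow(x$pixels), ncol(x$pixels),
              if (is.null(x$dpi)) "unknown" else format(x$dpi),
              if (nzchar(x$source_path)) x$source_path else "<memory>"))
  invisible(x)
}

# ITU-R BT.601 luminance weights; scanned pen drawings carry no hue signal.
.rgb_to_gray <- function(arr) {
  if (length(dim(arr)) == 2) return(arr)
  nch <- dim(arr)[3]
  if (nch >= 3)
    0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  else
    arr[, , 1]
}

#' Load a scanned drawing
#'
#' Reads a PNG, TIFF or JPEG scan, converts RGB to grayscale by luminance
#' weighting, and populates `dpi` from embedded resolution metadata when the
#' file carries it (PNG pHYs chunk, TIFF resolution tags). JPEG files are
#' read without resolution metadata.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @return a [raster_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop_treedraw(sprintf("cannot read '%s': no such file", path),
                  "treedraw_io_error")
  ext <- tolower(tools::file_ext(path))
  read_one <- function() {
    switch(ext,
      png = {
        img <- png::readPNG(path, info = TRUE)
        info <- attr(img, "info")
        dpi <- if (!is.null(info$dpi) && all(is.finite(info$dpi)) &&
                   all(info$dpi > 0)) mean(info$dpi)
        list(arr = img, dpi = dpi)
      },
      tif = ,
      tiff = {
        img <- tiff::readTIFF(path, info = TRUE)
        info <- attr(img, "info")
        res <- info$x.resolution
        dpi <- NULL
        if (!is.null(res) && is.finite(res) && res > 0) {
          unit <- info$resolution.unit
          # TIFF resolution may be per-inch (default) or per-cm
          dpi <- if (!is.null(unit) && identical(unit, "cm")) res * 2.54
                 else res
        }
        list(arr = img, dpi = dpi)
      },
      jpg = ,
      jpeg = list(arr = jpeg::readJPEG(path), dpi = NULL),
      stop_treedraw(sprintf("unsupported image format '.%s'", ext),
                    "treedraw_io_error")
    )
  }
  got <- tryCatch(read_one(), error = function(e) {
    if (inherits(e, "treedraw_error")) stop(e)
    stop_treedraw(sprintf("cannot read '%s': %s", path,
                          conditionMessage(e)), "treedraw_io_error")
  })
  dpi <- got$dpi
  gray <- .rgb_to_gray(got$arr)
  if (is.null(dim(gray)) || any(dim(gray) < 1))
    stop_treedraw("image has zero dimension", "treedraw_format_error")
  px <- gray * 255
  attributes(px) <- list(dim = dim(gray))  # drop reader metadata attrs
  raster_image(pixels = px, dpi = dpi, source_path = path)
}

#' Write a raster image to a PNG file
#'
#' The inverse of [load_image()] for PNG output; dpi metadata, when present,
#' is embedded so calibration survives a write/read round trip.
#'
#' @param image a [raster_image()].
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "raster_image"))
  px <- pmin(pmax(image$pixels / 255, 0), 1)
  if (is.null(image$dpi)) png::writePNG(px, path)
  else png::writePNG(px, path, dpi = image$dpi)
  invisible(path)
}

#' Derive pixel-to-centimetre calibration
#'
#' Pixel measurements become physical units through a single scale factor.
#' When the scan carries dpi metadata, `pixels_per_cm = dpi / 2.54`.
#' Otherwise the page is assumed to be A4 and the factor is fitted from the
#' page width: `cols / page_width_cm`, with landscape pages (cols > rows)
#' fitted to 29.7 cm instead of 21.0 cm.
#'
#' @param image a [raster_image()].
#' @param page_width_cm physical page width used for the page-fit fallback;
#'   default 21.0 (A4 portrait). Ignored when dpi metadata is present.
#' @param strict if `TRUE`, refuse the page-fit fallback and error unless
#'   dpi metadata is available.
#' @return an object of class `calibration` with fields `pixels_per_cm` and
#'   `source` (one of `"dpi-metadata"`, `"page-fit"`, `"manual"`).
#' @export
derive_calibration <- function(image, page_width_cm = 21.0, strict = FALSE) {
  stopifnot(inherits(image, "raster_image"))
  if (!is.null(image$dpi)) {
    return(calibration(image$dpi / 2.54, source = "dpi-metadata"))
  }
  if (strict || is.null(page_width_cm))
    stop_treedraw("no dpi metadata and page-width fitting disallowed",
                  "treedraw_calibration_error")
  if (!is_scalar_number(page_width_cm) || page_width_cm <= 0)
    stop_treedraw("page_width_cm must be a positive number",
                  "treedraw_calibration_error")
  cols <- ncol(image$pixels)
  rows <- nrow(image$pixels)
  # landscape scan: the long (29.7 cm) side is horizontal
  width_cm <- if (cols > rows) page_width_cm * 29.7 / 21.0 else page_width_cm
  calibration(cols / width_cm, source = "page-fit")
}

#' Construct a calibration object
#'
#' @param pixels_per_cm positive scale factor.
#' @param source how the factor was obtained: `"dpi-metadata"`, `"page-fit"`
#'   or `"manual"`.
#' @return an object of class `calibration`.
#' @export
calibration <- function(pixels_per_cm,
                        source = c("manual", "dpi-metadata", "page-fit")) {
  source <- match.arg(source)
  if (!is_scalar_number(pixels_per_cm) || pixels_per_cm <= 0)
    stop_treedraw("pixels_per_cm must be finite and positive",
                  "treedraw_calibration_error")
  structure(list(pixels_per_cm = pixels_per_cm, source = source),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.4f px/cm (%s)\n", x$pixels_per_cm, x$source))
  invisible(x)
}
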