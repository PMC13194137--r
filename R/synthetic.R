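# Synthetic tree-drawing renderer with analytic ground truth.
#
# Patient scans from drawing-test studies are never deposited, so validation
# rests on a generator whose geometry is known exactly: a (jittered) ellipse
# crown atop a trapezoidal trunk with an optional trapezoidal root flare,
# drawn filled or as outline strokes on a white A4 page, with optional
# scanner noise and a handwritten-annotation stand-in near the page edge.
# Ground-truth masks come from the same geometry that drew the ink, and
# ground-truth metrics from closed-form areas (pi*a*b, trapezoid rule).

A4_WIDTH_CM <- 21.0
A4_HEIGHT_CM <- 29.7

#' Specify a synthetic tree drawing
#'
#' @param crown_semi_axes_cm horizontal and vertical semi-axes (a, b) of the
#'   elliptical crown, cm.
#' @param crown_jitter fractional radial jitter amplitude of the crown
#'   boundary (0 = exact ellipse); smooth low-order harmonics, seeded.
#' @param trunk_top_cm,trunk_bottom_cm trunk width at the crown junction and
#'   at the base, cm (a trapezoid; equal values give a rectangle).
#' @param trunk_height_cm trunk height, cm.
#' @param root root flare, or `NULL` for none: a list with `flare` (base
#'   width as a multiple of `trunk_bottom_cm`, > 1) and `length_cm`.
#' @param style `"filled"` (solid silhouette ink) or `"outline"` (strokes of
#'   `stroke_px` thickness along the component contours).
#' @param stroke_px outline stroke thickness in pixels.
#' @param noise_sigma additive Gaussian scanner noise, grayscale sd on the
#'   0-255 scale.
#' @param annotation if `TRUE`, draw short text-like dashes 4% from the
#'   bottom page edge (the protocol has participants write age and sex on
#'   the page).
#' @param dpi raster resolution; page is always A4 portrait.
#' @param seed integer seed; all randomness (jitter, noise) flows from it.
#' @return an object of class `synthetic_tree_spec`.
#' @export
synthetic_tree_spec <- function(crown_semi_axes_cm = c(3, 2.4),
                                crown_jitter = 0.05,
                                trunk_top_cm = 1.4, trunk_bottom_cm = 1.7,
                                trunk_height_cm = 6,
                                root = NULL,
                                style = c("filled", "outline"),
                                stroke_px = 2,
                                noise_sigma = 0,
                                annotation = FALSE,
                                dpi = 300, seed = 1) {
  style <- match.arg(style)
  a <- crown_semi_axes_cm[1]; b <- crown_semi_axes_cm[2]
  stopifnot(a > 0, b > 0, trunk_top_cm > 0, trunk_bottom_cm > 0,
            trunk_height_cm > 0, crown_jitter >= 0, stroke_px >= 1,
            noise_sigma >= 0, dpi > 0)
  if (!is.null(root)) {
    stopifnot(is.list(root), root$flare > 1, root$length_cm > 0)
  }
  spec <- structure(list(
    crown_a_cm = a, crown_b_cm = b, crown_jitter = crown_jitter,
    trunk_top_cm = trunk_top_cm, trunk_bottom_cm = trunk_bottom_cm,
    trunk_height_cm = trunk_height_cm, root = root,
    style = style, stroke_px = stroke_px, noise_sigma = noise_sigma,
    annotation = annotation, dpi = dpi, seed = as.integer(seed)),
    class = "synthetic_tree_spec")
  root_len <- if (is.null(root)) 0 else root$length_cm
  total_h <- 2 * b + trunk_height_cm + root_len
  width <- max(2 * a, if (is.null(root)) trunk_bottom_cm
               else root$flare * trunk_bottom_cm)
  if (total_h > A4_HEIGHT_CM - 2 || width > A4_WIDTH_CM - 2)
    stop_treedraw("tree geometry exceeds the A4 page",
                  "treedraw_spec_error")
  spec
}

# Smooth periodic jitter profile: low-order harmonics, normalized so the
# maximum absolute deviation equals the requested amplitude.
.jitter_fun <- function(amp, seed) {
  if (amp == 0) return(function(theta) rep(0, length(theta)))
  co <- with_seed(seed, rnorm(10))
  raw <- function(theta) {
    out <- 0
    for (k in 2:6) {
      out <- out + co[2 * (k - 2) + 1] * cos(k * theta) +
                   co[2 * (k - 2) + 2] * sin(k * theta)
    }
    out
  }
  mx <- max(abs(raw(seq(0, 2 * pi, length.out = 720))))
  function(theta) amp * raw(theta) / mx
}

#' Render a synthetic tree drawing
#'
#' Deterministic given the spec's seed. The returned ground truth uses the
#' same geometry that produced the ink: `segmentation` holds the exact
#' rasterized crown/trunk/root masks and boundary rows, `metrics` the
#' closed-form measurements (ellipse area `pi*a*b`, trapezoid areas), and
#' `metrics_raster` the calibrated measurements of the ground-truth masks
#' themselves (rasterization included, pipeline excluded).
#'
#' @param spec a [synthetic_tree_spec()].
#' @return list with `image` ([raster_image()] with dpi set), `ink`
#'   (logical ground-truth ink mask before noise), `segmentation`,
#'   `metrics`, `metrics_raster`, and `spec`.
#' @export
render_tree <- function(spec) {
  stopifnot(inherits(spec, "synthetic_tree_spec"))
  ppcm <- spec$dpi / 2.54
  nc <- round(A4_WIDTH_CM * ppcm)
  nr <- round(A4_HEIGHT_CM * ppcm)
  a_px <- spec$crown_a_cm * ppcm
  b_px <- spec$crown_b_cm * ppcm
  trunk_h_px <- round(spec$trunk_height_cm * ppcm)
  root_len_px <- if (is.null(spec$root)) 0L
                 else round(spec$root$length_cm * ppcm)
  total_px <- 2 * b_px + trunk_h_px + root_len_px
  cx <- (nc + 1) / 2
  top <- max(2, (nr - total_px) / 2)
  cy <- top + b_px
  junction <- round(cy + b_px)           # first trunk row
  root_row <- junction + trunk_h_px      # first root row (sentinel if none)

  sil <- matrix(FALSE, nr, nc)

  # crown: jittered ellipse, clipped to rows above the junction
  jit <- .jitter_fun(spec$crown_jitter, spec$seed)
  rmax <- 1 + spec$crown_jitter
  r_lo <- max(1, floor(cy - rmax * b_px)); r_hi <- junction - 1
  c_lo <- max(1, floor(cx - rmax * a_px))
  c_hi <- min(nc, ceiling(cx + rmax * a_px))
  rr <- r_lo:r_hi; cc <- c_lo:c_hi
  yy <- matrix(rr - cy, length(rr), length(cc))
  xx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
  u <- xx / a_px; v <- yy / b_px
  theta <- atan2(v, u)
  inside <- u^2 + v^2 <= (1 + jit(theta))^2
  sil[rr, cc] <- sil[rr, cc] | inside

  # trunk: trapezoid, width linear from top to bottom
  if (trunk_h_px >= 1) {
    t_rows <- junction:(junction + trunk_h_px - 1)
    frac <- if (trunk_h_px == 1) 0 else
      (t_rows - junction) / (trunk_h_px - 1)
    halfw <- (spec$trunk_top_cm +
              (spec$trunk_bottom_cm - spec$trunk_top_cm) * frac) * ppcm / 2
    for (i in seq_along(t_rows)) {
      lo <- max(1, ceiling(cx - halfw[i])); hi <- min(nc, floor(cx + halfw[i]))
      if (hi >= lo) sil[t_rows[i], lo:hi] <- TRUE
    }
  }

  # root flare: trapezoid widening downward
  if (root_len_px >= 1) {
    r_rows <- root_row:(root_row + root_len_px - 1)
    frac <- if (root_len_px == 1) 1 else
      (r_rows - root_row + 1) / root_len_px
    w0 <- spec$trunk_bottom_cm
    halfw <- (w0 + (spec$root$flare - 1) * w0 * frac) * ppcm / 2
    for (i in seq_along(r_rows)) {
      lo <- max(1, ceiling(cx - halfw[i])); hi <- min(nc, floor(cx + halfw[i]))
      if (hi >= lo) sil[r_rows[i], lo:hi] <- TRUE
    }
  }

  ink <- if (spec$style == "filled") sil else {
    er <- EBImage::erode(sil * 1,
                         EBImage::makeBrush(2 * spec$stroke_px + 1,
                                            shape = "disc")) > 0.5
    sil & !er
  }

  if (spec$annotation) {
    # handwriting stand-in: dashes centered 4% above the bottom edge
    t_r <- round(nr * 0.96)
    dash_h <- max(2, round(0.12 * ppcm))
    dash_w <- max(4, round(0.45 * ppcm))
    gap <- max(3, round(0.2 * ppcm))
    x0 <- round(nc * 0.12)
    for (k in 0:3) {
      cs <- x0 + k * (dash_w + gap)
      ink[t_r:(t_r + dash_h - 1), cs:(cs + dash_w - 1)] <- TRUE
    }
  }

  page <- matrix(255, nr, nc)
  page[ink] <- 0

  if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed + 1L,
                       rnorm(length(page), 0, spec$noise_sigma))
    page <- pmin(pmax(page + noise, 0), 255)
    page <- matrix(page, nr, nc)
  }

  trunk_root_row <- if (root_len_px >= 1) root_row else nr + 1L
  seg <- segment_tree(sil, list(crown_trunk_row = junction,
                                trunk_root_row = trunk_root_row,
                                flags = character(0)))
  cal <- calibration(ppcm, source = "manual")
  metrics <- render_truth_metrics(spec)
  list(image = raster_image(page, dpi = spec$dpi, source_path = "<render>"),
       ink = ink,
       segmentation = seg,
       metrics = metrics,
       metrics_raster = measure(seg, cal),
       spec = spec)
}

#' Specify a synthetic cohort
#'
#' Per-group marginal distributions of total drawn area, crown:trunk area
#' ratio, and HDRS/HAMA scores, plus a rank correlation `rho` between total
#' area and HDRS induced within each group through a Gaussian copula. The
#' default groups mirror the study conditions reported for depressed
#' adolescents, depressed adults and healthy controls (group sizes, total
#' areas, scale scores); the correlation default -0.3 matches the reported
#' direction and magnitude class of the area-severity association.
#'
#' @param groups named list; each element a list with `n`, `area_mean`,
#'   `area_sd` (total area, cm^2), `ratio_mean`, `ratio_sd` (crown:trunk),
#'   `hdrs_mean`, `hdrs_sd`, `hama_mean`, `hama_sd` (NA allowed),
#'   `age_range` (years).
#' @param rho Spearman-scale rank correlation between total area and HDRS
#'   within each group, in \[-1, 1\].
#' @param dpi raster resolution for rendered cohort images.
#' @param seed master seed; every participant's geometry, scores and image
#'   derive from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = NULL, rho = -0.3, dpi = 150, seed = 1) {
  if (is.null(groups)) {
    groups <- list(
      "depressed-adolescent" = list(
        n = 82, area_mean = 54.61, area_sd = 5.03,
        ratio_mean = 2.2, ratio_sd = 0.3,
        hdrs_mean = 26.73, hdrs_sd = 9.03,
        hama_mean = 22.36, hama_sd = 1.17, age_range = c(12, 17)),
      "depressed-adult" = list(
        n = 43, area_mean = 56.71, area_sd = 4.20,
        ratio_mean = 5.1, ratio_sd = 0.6,
        hdrs_mean = 39.63, hdrs_sd = 3.31,
        hama_mean = 7.05, hama_sd = 0.29, age_range = c(18, 65)),
      "control" = list(
        n = 59, area_mean = 114.53, area_sd = 9.53,
        ratio_mean = 4.7, ratio_sd = 0.6,
        hdrs_mean = 4.80, hdrs_sd = 2.83,
        hama_mean = NA, hama_sd = NA, age_range = c(18, 65)))
  }
  stopifnot(length(groups) >= 1, !is.null(names(groups)),
            abs(rho) <= 1, dpi > 0)
  for (g in groups) stopifnot(g$n >= 1, g$area_sd >= 0, g$ratio_sd >= 0,
                              g$hdrs_sd >= 0)
  structure(list(groups = groups, rho = rho, dpi = dpi,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Geometry for one participant from total area and crown:trunk ratio.
# Crown ellipse aspect a = 1.15 b; trunk a near-rectangle with height = 4 x
# width and a slight taper. No roots: the area split is then exact.
.tree_spec_from_area <- function(area, ratio, jitter, dpi, seed) {
  crown_area <- area * ratio / (1 + ratio)
  trunk_area <- area / (1 + ratio)
  b <- sqrt(crown_area / (pi * 1.15))
  a <- 1.15 * b
  w <- sqrt(trunk_area / 4)
  synthetic_tree_spec(crown_semi_axes_cm = c(a, b), crown_jitter = jitter,
                      trunk_top_cm = w * 0.95, trunk_bottom_cm = w * 1.05,
                      trunk_height_cm = trunk_area / w,
                      style = "filled", noise_sigma = 4,
                      dpi = dpi, seed = seed)
}

#' Generate a synthetic cohort
#'
#' Draws per-participant total areas, crown:trunk ratios and scale scores
#' from the cohort spec (area and HDRS linked by a Gaussian copula at the
#' requested rank correlation), derives a drawing geometry for each
#' participant, and optionally renders and writes the page images.
#'
#' @param cohort a [cohort_spec()].
#' @param output_dir directory for `roster.csv`, `truth.csv` and
#'   `images/<id>.png`; `NULL` writes nothing and returns the tables only.
#' @param render_images render and write PNG pages (requires `output_dir`).
#' @return invisibly, a list with `roster` (id, group, age, sex, education,
#'   hdrs, hama) and `truth` (id plus ground-truth metric columns).
#' @export
generate_cohort <- function(cohort, output_dir = NULL,
                            render_images = !is.null(output_dir)) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (render_images && is.null(output_dir))
    stop_treedraw("rendering requires an output directory",
                  "treedraw_io_error")
  if (!is.null(output_dir)) {
    ok <- dir.exists(output_dir) || dir.create(output_dir, recursive = TRUE,
                                               showWarnings = FALSE)
    if (!ok || file.access(output_dir, 2) != 0)
      stop_treedraw(sprintf("cannot write to '%s'", output_dir),
                    "treedraw_io_error")
  }
  edu_levels <- c("primary", "junior-high", "high-school", "college")
  rows <- list(); truths <- list(); specs <- list()
  idx <- 0
  for (gname in names(cohort$groups)) {
    g <- cohort$groups[[gname]]
    gi <- match(gname, names(cohort$groups))
    draws <- with_seed(cohort$seed + 7919L * gi, {
      z1 <- rnorm(g$n)
      z2 <- cohort$rho * z1 + sqrt(1 - cohort$rho^2) * rnorm(g$n)
      list(z1 = z1, z2 = z2, zr = rnorm(g$n),
           age = round(runif(g$n, g$age_range[1], g$age_range[2])),
           sex = sample(c("male", "female"), g$n, replace = TRUE),
           edu = sample(edu_levels, g$n, replace = TRUE,
                        prob = c(0.04, 0.15, 0.73, 0.08)),
           hama_z = rnorm(g$n))
    })
    for (i in seq_len(g$n)) {
      idx <- idx + 1
      id <- sprintf("S%03d", idx)
      area <- max(15, g$area_mean + g$area_sd * draws$z1[i])
      hdrs <- max(0, round(g$hdrs_mean + g$hdrs_sd * draws$z2[i]))
      ratio <- max(0.6, g$ratio_mean + g$ratio_sd * draws$zr[i])
      hama <- if (is.na(g$hama_mean)) NA_real_ else
        max(0, round(g$hama_mean + g$hama_sd * draws$hama_z[i]))
      pseed <- as.integer((cohort$seed * 131L + idx * 2654435L) %% 2147483647L)
      spec <- .tree_spec_from_area(area, ratio, jitter = 0.04,
                                   dpi = cohort$dpi, seed = pseed)
      specs[[id]] <- spec
      rows[[id]] <- data.frame(id = id, group = gname,
                               age = draws$age[i], sex = draws$sex[i],
                               education = draws$edu[i],
                               hdrs = hdrs, hama = hama,
                               stringsAsFactors = FALSE)
      tm <- render_truth_metrics(spec)
      truths[[id]] <- cbind(data.frame(id = id, stringsAsFactors = FALSE),
                            metrics_as_row(tm, digits = NULL)[
                              , setdiff(names(metrics_as_row(tm)), "flags")])
    }
  }
  roster <- do.call(rbind, rows)
  truth <- do.call(rbind, truths)
  rownames(roster) <- rownames(truth) <- NULL
  if (!is.null(output_dir)) {
    write.csv(roster, file.path(output_dir, "roster.csv"),
              row.names = FALSE)
    write.csv(truth, file.path(output_dir, "truth.csv"), row.names = FALSE)
    if (render_images) {
      img_dir <- file.path(output_dir, "images")
      dir.create(img_dir, showWarnings = FALSE)
      for (id in roster$id) {
        out <- render_tree(specs[[id]])
        write_image(out$image, file.path(img_dir, paste0(id, ".png")))
      }
    }
  }
  invisible(list(roster = roster, truth = truth, specs = specs))
}

# Analytic ground-truth metrics of a spec without rasterizing the page.
render_truth_metrics <- function(spec) {
  root_area <- if (is.null(spec$root)) 0 else {
    w0 <- spec$trunk_bottom_cm
    (w0 + spec$root$flare * w0) / 2 * spec$root$length_cm
  }
  tree_metrics(
    crown_area_cm2 = pi * spec$crown_a_cm * spec$crown_b_cm,
    trunk_area_cm2 = (spec$trunk_top_cm + spec$trunk_bottom_cm) / 2 *
                     spec$trunk_height_cm,
    root_area_cm2 = root_area,
    crown_height_cm = 2 * spec$crown_b_cm,
    trunk_height_cm = spec$trunk_height_cm,
    root_height_cm = if (is.null(spec$root)) 0 else spec$root$length_cm,
    crown_width_cm = 2 * spec$crown_a_cm,
    trunk_width_cm = max(spec$trunk_top_cm, spec$trunk_bottom_cm),
    root_width_cm = if (is.null(spec$root)) 0
                    else spec$root$flare * spec$trunk_bottom_cm)
}
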