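# Silhouette construction and crown/trunk/root partitioning.
#
# The partition is row-based: the silhouette's per-row horizontal extent
# (its width profile) is wide over the crown, drops to a narrow plateau over
# the trunk, and may widen again where root flares spread at the page
# baseline. Change points in the smoothed profile define the two boundary
# rows; the silhouette is then split exactly along them, which makes the
# partition identity |crown| + |trunk| + |roots| = |silhouette| hold by
# construction.

#' Fill a drawing component into a solid silhouette
#'
#' Morphological closing (to seal small contour gaps) followed by hole
#' filling: an outline-style drawing becomes the solid region it encloses.
#' Area measurements are defined on this filled silhouette, not on the ink
#' strokes themselves.
#'
#' @param component a `component_mask` from [largest_component()].
#' @param closing_radius_px disc radius for the pre-fill closing (default 3).
#' @return a logical matrix, the filled silhouette.
#' @export
fill_silhouette <- function(component, closing_radius_px = 3) {
  stopifnot(inherits(component, "component_mask"))
  m <- component$mask
  if (closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius_px + 1, shape = "disc")
    m <- EBImage::closing(m * 1, brush) > 0.5
  }
  filled <- EBImage::fillHull(m * 1L) > 0L
  matrix(as.logical(filled), nrow(m), ncol(m))
}

#' Per-row width profile of a silhouette
#'
#' For every row in the silhouette's vertical range, records the filled
#' pixel count and the horizontal extent (rightmost - leftmost + 1), plus a
#' centered moving-average smoothing of the extent used by the boundary
#' finder.
#'
#' @param silhouette logical matrix.
#' @param smooth_window_rows odd window length in rows; default
#'   `max(3, 2%)` of the silhouette height, forced odd.
#' @return an object of class `width_profile` with fields `rows` (absolute
#'   row indices), `count`, `extent`, `smoothed`, `window`.
#' @export
width_profile <- function(silhouette, smooth_window_rows = NULL) {
  stopifnot(is.matrix(silhouette))
  sil <- silhouette > 0
  rows_present <- which(rowSums(sil) > 0)
  if (length(rows_present) == 0)
    stop_treedraw("empty silhouette", "treedraw_no_drawing_error")
  r0 <- rows_present[1]
  r1 <- rows_present[length(rows_present)]
  rows <- r0:r1
  sub <- sil[rows, , drop = FALSE]
  count <- rowSums(sub)
  extent <- apply(sub, 1, function(v) {
    w <- which(v)
    if (length(w) == 0) 0 else w[length(w)] - w[1] + 1L
  })
  h <- length(rows)
  if (is.null(smooth_window_rows))
    smooth_window_rows <- max(3, round(0.02 * h))
  if (smooth_window_rows %% 2 == 0)
    smooth_window_rows <- smooth_window_rows + 1
  smoothed <- .moving_average(extent, smooth_window_rows)
  structure(list(rows = rows, count = count, extent = extent,
                 smoothed = smoothed, window = smooth_window_rows),
            class = "width_profile")
}

# Centered moving average with window shrinking at the ends (no phase shift,
# no NA padding).
.moving_average <- function(x, w) {
  n <- length(x)
  half <- (w - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Locate the crown/trunk and trunk/root boundary rows
#'
#' Two-stage change-point detection on the smoothed width profile.
#'
#' Crown/trunk — coarse stage: starting below the row of maximum smoothed
#' extent, find the first run of at least `run_rows` consecutive rows whose
#' smoothed extent is at most `alpha` times the maximum, i.e. where the wide
#' crown has collapsed toward the narrow trunk. Refinement: a width
#' threshold relative to the *crown* fires where the shrinking crown chord
#' crosses it, a little above the true junction, so the boundary is first
#' walked down to where the smoothed extent reaches the trunk plateau
#' (1.15 times the median extent below the run start) and then snapped to
#' the raw-extent minimum in a short window — the crown chord pinches to
#' nearly nothing right at the junction, making that minimum the junction
#' row itself.
#' If no coarse run exists (a degenerate profile), the boundary falls back
#' to the first row below the maximum whose extent drops under `alpha`
#' times the maximum (or the top row if none), and the result is flagged
#' low-confidence.
#'
#' Trunk/root — coarse stage: with `m` the median smoothed extent from the
#' crown/trunk boundary down, root flares appear as the deepest maximal run
#' of rows with smoothed extent at least `beta * m`, provided that run
#' reaches into the bottom quarter of the trunk region. Refinement: the
#' `beta` threshold only fires part-way down a gradually widening flare,
#' so the onset is walked up on the raw extent while the backward jump
#' over a few rows is steeper than anything the trunk's own taper
#' produces. No qualifying run means no roots; the boundary is then one
#' past the bottom row (sentinel).
#'
#' @param profile a [width_profile()].
#' @param alpha crown-collapse fraction, in (0, 1); default 0.45.
#' @param beta root-flare multiple of the trunk median, > 1; default 1.6.
#' @param run_rows minimum run length in rows; default `max(3, 1%)` of the
#'   silhouette height.
#' @return list with `crown_trunk_row`, `trunk_root_row` (absolute row
#'   indices; `trunk_root_row = bottom + 1` means no roots) and `flags`
#'   (character vector, possibly containing `"low-confidence-boundary"`).
#' @export
find_boundaries <- function(profile, alpha = 0.45, beta = 1.6,
                            run_rows = NULL) {
  stopifnot(inherits(profile, "width_profile"))
  if (!(alpha > 0 && alpha < 1)) stop_treedraw("alpha must be in (0,1)",
                                               "treedraw_config_error")
  if (!(beta > 1)) stop_treedraw("beta must exceed 1",
                                 "treedraw_config_error")
  sm <- profile$smoothed
  rows <- profile$rows
  n <- length(rows)
  if (is.null(run_rows)) run_rows <- max(3, round(0.01 * n))
  flags <- character(0)

  imax <- which.max(sm)
  thr <- alpha * sm[imax]
  below <- if (imax < n) seq(imax + 1, n) else integer(0)
  low <- sm[below] <= thr
  ct_i <- .first_run_start(low, run_rows)
  if (!is.na(ct_i)) {
    crown_trunk_i <- below[ct_i]
    # refine 1: walk down to where the profile meets the trunk plateau
    if (crown_trunk_i < n) {
      plateau <- 1.15 * median(sm[crown_trunk_i:n])
      hit <- which(sm[crown_trunk_i:n] <= plateau)
      if (length(hit)) crown_trunk_i <- crown_trunk_i + hit[1] - 1L
    }
    # refine 2: the crown chord pinches just above the junction, so the
    # raw-extent minimum in a short window marks the junction itself
    win_end <- min(n, crown_trunk_i + max(run_rows, profile$window))
    win <- crown_trunk_i:win_end
    crown_trunk_i <- win[which.min(profile$extent[win])]
  } else {
    flags <- c(flags, "low-confidence-boundary")
    drop_i <- which(sm[below] < thr)
    crown_trunk_i <- if (length(drop_i)) below[drop_i[1]] else 1L
  }

  trunk_i <- crown_trunk_i:n
  med <- median(sm[trunk_i])
  wide <- sm[trunk_i] >= beta * med
  runs <- .runs_of(wide)
  trunk_root_i <- n + 1L
  if (nrow(runs)) {
    deepest <- runs[nrow(runs), ]
    q_start <- length(trunk_i) - floor(length(trunk_i) / 4) + 1
    if (deepest["end"] >= q_start) {
      onset <- deepest[["start"]]
      # refine: the beta threshold fires part-way down the flare; walk up
      # on the raw extent while the backward k-row jump is steeper than
      # anything the trunk's own taper produces
      k <- max(3L, min(run_rows, 10L))
      ext <- profile$extent[trunk_i]
      while (onset > k + 1 && ext[onset] - ext[onset - k] > 3)
        onset <- onset - 1L
      trunk_root_i <- trunk_i[onset]
    }
  }
  list(crown_trunk_row = rows[1] + crown_trunk_i - 1L,
       trunk_root_row = rows[1] + trunk_root_i - 1L,
       flags = flags)
}

# Index (within x) of the first element starting a TRUE-run of length >= k.
.first_run_start <- function(x, k) {
  if (length(x) == 0) return(NA_integer_)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= k)
  if (length(hit) == 0) NA_integer_ else starts[hit[1]]
}

# All maximal TRUE-runs as a matrix with columns start, end.
.runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  cbind(start = starts[keep], end = ends[keep])[seq_along(keep), ,
                                                drop = FALSE]
}

#' Partition a silhouette into crown, trunk and roots
#'
#' Splits the filled silhouette along the two boundary rows: crown pixels
#' lie strictly above `crown_trunk_row`, root pixels at or below
#' `trunk_root_row`, trunk pixels between. The three masks are disjoint and
#' their union is exactly the silhouette.
#'
#' @param silhouette logical matrix.
#' @param boundaries list from [find_boundaries()] (or a list with the same
#'   fields).
#' @return an object of class `tree_segmentation` with fields
#'   `silhouette_mask`, `crown_mask`, `trunk_mask`, `root_mask`,
#'   `crown_trunk_row`, `trunk_root_row`, `flags`.
#' @export
segment_tree <- function(silhouette, boundaries) {
  sil <- silhouette > 0
  ct <- boundaries$crown_trunk_row
  tr <- boundaries$trunk_root_row
  if (tr < ct)
    stop_treedraw("inverted boundaries: trunk_root_row < crown_trunk_row",
                  "treedraw_internal_error")
  nr <- nrow(sil)
  rowidx <- row(sil)
  crown <- sil & rowidx < ct
  trunk <- sil & rowidx >= ct & rowidx < tr
  root  <- sil & rowidx >= tr
  structure(list(silhouette_mask = sil,
                 crown_mask = crown, trunk_mask = trunk, root_mask = root,
                 crown_trunk_row = ct, trunk_root_row = tr,
                 flags = if (is.null(boundaries$flags)) character(0)
                         else boundaries$flags),
            class = "tree_segmentation")
}

#' @export
print.tree_segmentation <- function(x, ...) {
  cat(sprintf(paste0("<tree_segmentation> silhouette %d px ",
                     "(crown %d, trunk %d, root %d); boundaries at rows ",
                     "%d / %s%s\n"),
              sum(x$silhouette_mask), sum(x$crown_mask), sum(x$trunk_mask),
              sum(x$root_mask), x$crown_trunk_row,
              if (sum(x$root_mask) == 0) "none (no roots)"
              else as.character(x$trunk_root_row),
              if (length(x$flags)) paste0(" [", paste(x$flags,
                                                      collapse = ", "), "]")
              else ""))
  invisible(x)
}
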